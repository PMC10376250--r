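alternative,IoU,ACC,RE,PR,F1,Params,GMACs,FPS
U-Net/ResNet50,94.96,97.29,97.31,97.27,97.29,32.52,10.7,24
U-Net/MobileNet v2,95.56,97.56,97.57,97.55,97.56,6.63,3.39,26
U-Net/EfficientNet-B1,96.53,98.14,98.16,98.12,98.14,8.76,2.53,22
UNet++/ResNet50,96.57,98.18,98.2,98.16,98.18,48.99,57.54,20
UNet++/MobileNet v2,96.27,98,98.03,97.98,98,6.82,4.5,26
UNet++/EfficientNet-B1,96.79,98.11,98.14,98.09,98.11,9.08,5.1,21
DeepLabv3/ResNet50,96.23,97.95,97.98,97.93,97.96,39.63,40.99,24
DeepLabv3/MobileNet v2,95.79,97.69,97.73,97.66,97.69,12.65,12.74,26
DeepLabv3/EfficientNet-B1,95.46,97.37,97.4,97.34,97.37,9.81,3.37,23
DeepLabv3+/ResNet50,96.25,97.97,98.02,97.93,97.97,26.68,9.2,26
DeepLabv3+/MobileNet v2,95.22,97.36,97.42,97.32,97.37,4.38,1.52,27
DeepLabv3+/EfficientNet-B1,95.93,97.75,97.83,97.7,97.76,7.41,0.56,23
PAN/ResNet50,96.06,97.87,98,97.78,97.89,8.71,24.26,26
PAN/MobileNet v2,95.17,97.27,97.5,97.14,97.31,2.42,0.79,26
PAN/EfficientNet-B1,91.83,95.09,98.86,92.71,95.52,6.6,0.09,22
LinkNet/ResNet50,96.31,98.03,98.03,98.03,98.03,31.18,10.77,26
LinkNet/MobileNet v2,95.11,97.32,97.33,97.32,97.32,4.32,0.94,26
LinkNet/EfficientNet-B1,96.32,98.04,98.08,98,98.04,3.67,0.19,22
MA-Net/ResNet50,96.34,98.03,98.06,98.01,98.03,147.44,18.64,21
MA-Net/MobileNet v2,96.23,97.98,98,97.96,97.98,48.89,5.27,24
MA-Net/EfficientNet-B1,96.57,98.15,98.16,98.14,98.15,11.6,2.41,21
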