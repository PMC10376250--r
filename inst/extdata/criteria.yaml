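# Criteria schema of the packaged 21-model benchmark.
# direction: benefit = larger is better, cost = smaller is better.
# weight: expert subjective weight (sums to 1 across criteria).
- name: IoU
  direction: benefit
  weight: 0.3
  level: segmentation accuracy
- name: ACC
  direction: benefit
  weight: 0.05
  level: segmentation accuracy
- name: RE
  direction: benefit
  weight: 0.05
  level: segmentation accuracy
- name: PR
  direction: benefit
  weight: 0.05
  level: segmentation accuracy
- name: F1
  direction: benefit
  weight: 0.05
  level: segmentation accuracy
- name: Params
  direction: cost
  weight: 0.1
  level: computational efficiency
- name: GMACs
  direction: cost
  weight: 0.1
  level: computational efficiency
- name: FPS
  direction: benefit
  weight: 0.3
  level: computational efficiency
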