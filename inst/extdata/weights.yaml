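# Default expert weight scheme: overlap accuracy (IoU) and inference speed
# (FPS) dominate; remaining accuracy metrics 0.05 each, complexity 0.1 each.
IoU: 0.3
ACC: 0.05
RE: 0.05
PR: 0.05
F1: 0.05
Params: 0.1
GMACs: 0.1
FPS: 0.3
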