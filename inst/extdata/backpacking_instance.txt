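10 265
31 21
141 97
46 32
30 21
74 52
105 75
119 86
160 116
59 43
71 54
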