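,A,B,C,D
A,0.9,0.1,0,0
B,0.6,0.3,0.1,0
C,0.2,0.4,0.4,0
D,0,0,0.2,0.8
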