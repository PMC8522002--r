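,A,B,C,D
A,0.4,0.3,0.2,0.1
B,0.1,0.3,0.4,0.2
C,0.1,0.2,0.3,0.4
D,0,0.1,0.3,0.6
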