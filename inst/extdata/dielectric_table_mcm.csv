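species,epsilon,Z
L,2.55,1.65
H,13.53,0.86
F,1.86,1.36
W,78.40,1.04
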