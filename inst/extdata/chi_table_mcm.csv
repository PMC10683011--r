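species,L,H,F,Proline,W
L,0,1.462,0.945,1.075,0.756
H,1.462,0,0.735,0.531,0.197
F,0.945,0.735,0,1.220,0.963
Proline,1.075,0.531,1.220,0,0.459
W,0.756,0.197,0.963,0.459,0
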