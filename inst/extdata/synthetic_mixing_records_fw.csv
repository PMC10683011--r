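species_i,species_j,Z,V_A3,E_kcal_mol,n
F,W,6,100,-1.904906165602,1
W,F,6,100,-1.904906165602,1
F,F,6,100,-2.0,1
W,W,6,100,-2.0,1
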