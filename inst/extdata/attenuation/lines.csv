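symbol,line,energy_keV,rel_intensity
Pd,Ka1,21.177,0.537
Pd,Ka2,21.02,0.286
Pd,Kb1,23.819,0.177
I,Ka1,28.612,0.525
I,Ka2,28.317,0.284
I,Kb1,32.295,0.191
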