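symbol,z,molar_mass,k_edge_keV,omega_k,k_jump
H,1,1.008,0.0136,NA,NA
C,6,12.011,0.284,NA,NA
N,7,14.007,0.41,NA,NA
O,8,15.999,0.543,NA,NA
Si,14,28.085,1.839,0.047,10.8
Pd,46,106.42,24.3503,0.82,6
I,53,126.904,33.1694,0.882,5.6
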