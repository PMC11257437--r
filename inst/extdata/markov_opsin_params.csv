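opsin,g0_nS,gamma,phim,k1,k2,p,q,Gf0,kf,Gb0,kb,Gd1,Gd2,Gr0,E_mV,v0_mV,v1_mV
ChR2,114,0.05,2.33e17,4.15,0.868,0.833,1.94,0.0373,0.0581,0.0161,0.063,0.105,0.0138,0.00033,0,43,17.1
ChR2-H134R,115,0.05,1.5e17,4.5,0.9,0.83,1.9,0.037,0.058,0.016,0.063,0.07,0.01,0.0003,0,43,17.1
Chrimson,60,0.05,2.0e17,3.0,0.8,0.8,1.9,0.037,0.058,0.016,0.063,0.067,0.01,0.0004,0,43,17.1
Vf-Chrimson,50,0.05,2.5e17,3.5,0.9,0.8,1.9,0.04,0.06,0.016,0.063,0.2,0.05,0.0005,0,43,17.1
GtACR2,200,0.05,2.0e17,4.0,0.9,0.83,1.9,0.037,0.058,0.016,0.063,0.09,0.012,0.0003,-70,43,17.1
eNpHR3.0,40,0.05,2.5e17,3.0,0.8,0.8,1.9,0.037,0.058,0.016,0.063,0.1,0.015,0.0004,-400,43,17.1
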