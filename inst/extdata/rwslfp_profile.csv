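lateral_um,amplitude,axial_lo_um,axial_hi_um,shape1,shape2
0,1.00,-400,800,2,3
100,0.80,-400,800,2,3
200,0.50,-400,800,2,3
300,0.25,-420,820,2,3
400,0.10,-440,840,2,3
600,0.00,-450,850,2,3
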