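opsin,wavelength_nm,epsilon
ChR2,400,0.55
ChR2,430,0.80
ChR2,450,0.95
ChR2,470,1.00
ChR2,490,0.85
ChR2,510,0.55
ChR2,530,0.30
ChR2,550,0.15
ChR2,570,0.05
ChR2,590,0.01
ChR2,610,0.00
ChR2-H134R,400,0.60
ChR2-H134R,430,0.90
ChR2-H134R,450,1.00
ChR2-H134R,470,0.95
ChR2-H134R,490,0.80
ChR2-H134R,510,0.50
ChR2-H134R,530,0.25
ChR2-H134R,550,0.10
ChR2-H134R,570,0.03
ChR2-H134R,590,0.01
ChR2-H134R,610,0.00
Chrimson,450,0.10
Chrimson,470,0.15
Chrimson,490,0.20
Chrimson,510,0.30
Chrimson,530,0.50
Chrimson,550,0.75
Chrimson,570,0.95
Chrimson,590,1.00
Chrimson,610,0.90
Chrimson,630,0.65
Chrimson,650,0.35
Chrimson,670,0.10
Vf-Chrimson,450,0.12
Vf-Chrimson,470,0.16
Vf-Chrimson,490,0.22
Vf-Chrimson,510,0.32
Vf-Chrimson,530,0.52
Vf-Chrimson,550,0.78
Vf-Chrimson,570,0.96
Vf-Chrimson,585,1.00
Vf-Chrimson,610,0.88
Vf-Chrimson,630,0.60
Vf-Chrimson,650,0.30
Vf-Chrimson,670,0.08
GtACR2,400,0.50
GtACR2,430,0.80
GtACR2,450,0.95
GtACR2,470,1.00
GtACR2,490,0.80
GtACR2,510,0.50
GtACR2,530,0.20
GtACR2,550,0.05
GtACR2,570,0.01
GtACR2,590,0.00
eNpHR3.0,450,0.05
eNpHR3.0,470,0.10
eNpHR3.0,490,0.20
eNpHR3.0,510,0.35
eNpHR3.0,530,0.60
eNpHR3.0,550,0.85
eNpHR3.0,570,0.97
eNpHR3.0,590,1.00
eNpHR3.0,610,0.85
eNpHR3.0,630,0.50
eNpHR3.0,650,0.20
eNpHR3.0,670,0.05
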