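wavelength_nm,K_per_mm,S_per_mm,n
473,0.125,7.37,1.36
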