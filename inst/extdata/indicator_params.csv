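indicator,Ca_rest_uM,gamma_per_s,kappa_S,dCa_T_uM,B_total_uM,Kd_uM,dFF_max,nH,dFF_1AP,sigma_noise,tau_on_ms,tau_off_ms
GCaMP6f,0.05,292.3,110,7.6,180,0.29,25.2,2.7,0.19,0.038,65,205
jGCaMP7,0.05,292.3,110,7.6,300,0.174,30.0,2.3,0.21,0.030,40,300
OGB-1,0.05,292.3,110,7.6,100,0.205,14.0,1.0,0.10,0.020,5,80
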