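cell_type,depth_rel_soma_um,amplitude_uV
excitatory,-600,0
excitatory,-400,-0.5
excitatory,-200,-1.4
excitatory,0,-2.0
excitatory,200,0.8
excitatory,400,1.6
excitatory,600,1.0
excitatory,800,0.4
excitatory,1000,0
inhibitory,-600,0
inhibitory,-400,0.3
inhibitory,-200,1.0
inhibitory,0,1.6
inhibitory,200,-0.6
inhibitory,400,-1.1
inhibitory,600,-0.6
inhibitory,800,-0.2
inhibitory,1000,0
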