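variant_id,kon_uM_s,kon_se,koff_s,koff_se,kd_nM,kd_se
WT,240,4,0.18,0.01,0.8,0.1
R266G,230,15,0.70,0.01,3.0,0.2
R266A,246,15,0.383,0.001,1.5,0.1
D267A,222,13,0.07,0.01,0.32,0.06
D267L,235,19,0.030,0.001,0.13,0.01
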