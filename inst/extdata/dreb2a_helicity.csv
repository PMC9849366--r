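variant_id,free_scs_ppm,free_percent,bound_scs_ppm,bound_percent,cd_percent,nmr_scale_percent
R266G,0.2,6,2.4,79,11,2
R266A,NA,NA,NA,NA,11,3
WT,0.5,17,2.9,94,13,5
D267A,NA,NA,NA,NA,17,11
D267L,1.6,51,3.1,100,19,14
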