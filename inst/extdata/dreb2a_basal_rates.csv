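variant_id,rate_kind,basal,basal_se
R266G,association,6,2
WT,association,5,2
D267L,association,10,2
WT,dissociation,5,1
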