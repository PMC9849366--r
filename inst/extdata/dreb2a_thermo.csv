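variant_id,kd_nM,kd_se,n,n_se,dh_kJmol,dh_se,minus_tds_kJmol,dg_kJmol
WT,84,9,0.84,0.02,-68,1,27.1,-40.4
R266G,369,27,0.85,0.02,-56,1,19.3,-36.9
D267L,66,13,0.91,0.09,-69.0,0.9,27.9,-41.1
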