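variant_id,rate_kind,nacl_mM,rate,rate_se
R266G,association,50,413,10
R266G,association,100,206,49
R266G,association,150,175,10
R266G,association,200,120,1
R266G,association,300,55.9,0.3
R266G,association,500,21.0,0.3
R266G,association,800,10.6,0.3
WT,association,50,335,64
WT,association,100,245,11
WT,association,150,118,4
WT,association,200,45,2
WT,association,300,36,2
WT,association,500,23.0,0.2
WT,association,800,8,1
D267L,association,100,178,35
D267L,association,150,149,19
D267L,association,200,142,9
D267L,association,300,81,3
D267L,association,500,45,1
D267L,association,800,22,1
R266G,dissociation,100,0.70,0.01
R266G,dissociation,800,5.29,0.05
WT,dissociation,100,0.18,0.01
WT,dissociation,200,0.40,0.01
WT,dissociation,300,0.53,0.02
WT,dissociation,500,0.94,0.01
WT,dissociation,800,1.78,0.02
D267L,dissociation,100,0.030,0.001
D267L,dissociation,800,0.223,0.004
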