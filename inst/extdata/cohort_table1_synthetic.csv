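sample_id,STIL_TAL1,CDKN2A_9p,del_6q,PTEN_cn,PTEN_exon7,NOTCH1,FBXW7,IL7R,FREM2,PIK3CD,LMO2
6030,mutation,loss,wt,wt,mutation,wt,wt,wt,mutation,wt,wt
6116,mutation,loss,wt,wt,wt,mutation,wt,wt,mutation,mutation,wt
CUL76,mutation,loss,wt,loss,wt,mutation,wt,wt,wt,wt,loss
CF5,mutation,loss,wt,loss,mutation,wt,wt,wt,wt,wt,wt
CF6,mutation,loss,loss,wt,wt,wt,wt,wt,wt,wt,wt
CF10,mutation,loss,wt,wt,mutation,wt,wt,wt,wt,wt,wt
HK328,mutation,loss,loss,wt,wt,wt,wt,wt,wt,wt,wt
BR75,mutation,loss,wt,wt,mutation,wt,wt,mutation,wt,wt,wt
BR74,mutation,loss,loss,wt,wt,wt,wt,wt,wt,wt,wt
S1,mutation,loss,loss,wt,wt,wt,wt,wt,wt,wt,wt
S2,mutation,loss,wt,wt,wt,mutation,wt,wt,wt,wt,wt
RPMI8402,mutation,loss,wt,loss,wt,wt,wt,wt,wt,wt,wt
CF7,mutation,loss,loss,wt,wt,wt,wt,wt,wt,wt,wt
CF8,mutation,loss,wt,loss,wt,wt,wt,wt,wt,wt,wt
CF9,mutation,loss,wt,wt,wt,mutation,wt,wt,wt,wt,wt
CF11,mutation,loss,loss,wt,wt,wt,wt,wt,wt,wt,wt
CF12,mutation,loss,wt,wt,mutation,wt,wt,wt,wt,wt,wt
CF13,mutation,wt,wt,wt,wt,wt,wt,wt,wt,wt,wt
CF14,mutation,loss,wt,wt,wt,wt,mutation,wt,wt,wt,wt
CF15,mutation,loss,wt,wt,wt,wt,wt,wt,wt,wt,wt
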