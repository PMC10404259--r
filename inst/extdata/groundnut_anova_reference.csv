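trait,source,df,ss,ms
pod_yield,Environment,2,3009690,1504845
pod_yield,Rep(Environment),3,1712,571
pod_yield,Genotype,29,158000,5448
pod_yield,GEI,58,471146,8123
pod_yield,PC1,30,409852,13662
pod_yield,PC2,28,61294,2189
pod_yield,Residuals,87,40359,464
rue,Environment,2,94802,47401
rue,Rep(Environment),3,68,23
rue,Genotype,29,7827,270
rue,GEI,58,22152,382
rue,PC1,30,16332,544
rue,PC2,28,5819,209
rue,Residuals,87,1770,20
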