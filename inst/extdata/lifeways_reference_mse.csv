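method,model,mse,mse_sd,r2
pca,nn,2.3271,0.0854,22.23
mice_pmm,nn,2.1106,0.1181,29.46
mice_norm,nn,2.2938,0.0965,23.34
reduction,nn,2.1662,1.0207,27.60
pca,linear,2.7083,0.0467,9.50
mice_pmm,linear,2.5674,0.0980,14.20
mice_norm,linear,2.6367,0.0780,11.88
reduction,linear,2.3033,0.9625,23.02
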