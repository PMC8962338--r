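# Published per-class classification counts of the two reference PTML models
# (MLP) and their linear-discriminant counterparts (LDA), training and test
# series. Inputs for the worked-example metric computations.
model,set,algorithm,n_active,ccc_active,n_inactive,ccc_inactive
1,train,mlp,3010,2495,4273,3817
1,test,mlp,1001,799,1421,1207
2,train,mlp,3010,2486,4273,3813
2,test,mlp,1001,785,1421,1195
1,train,lda,3010,1293,4273,3693
1,test,lda,1001,447,1421,1219
2,train,lda,3010,1084,4273,3625
2,test,lda,1001,352,1421,1194
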