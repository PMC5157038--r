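band,role,imi,mean,sd,n,reported_f
alpha,contra,3,51.41,13.61,20,8.25
alpha,contra,2,42.81,17.87,20,8.25
alpha,contra,1,31.58,14.97,20,8.25
alpha,ipsi,3,49.70,16.73,20,9.75
alpha,ipsi,2,42.84,16.33,20,9.75
alpha,ipsi,1,28.51,13.16,20,9.75
beta,contra,3,47.33,17.05,20,3.74
beta,contra,2,45.25,16.29,20,3.74
beta,contra,1,29.85,15.41,20,3.74
beta,ipsi,3,38.20,11.36,20,6.34
beta,ipsi,2,38.77,12.12,20,6.34
beta,ipsi,1,23.31,6.84,20,6.34
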