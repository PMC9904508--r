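trait,qtl,chrom,lod,cm_start,cm_end,mb_start,mb_end,pve_pct,additive
W2SES,qW2SES2.1,chr02,7.32,75.68,79.81,21.94,23.11,12.5,0.24
W2SES,qW2SES6.1,chr06,6.46,34.05,44.79,4.13,5.61,11.1,0.22
W2SES,qW2SES11.1,chr11,9.43,36.63,40.57,6.65,7.63,15.8,0.26
W2SES,qW2SES11.2,chr11,5.97,57.42,67.57,18.62,20.74,10.3,0.22
W4SES,qW4SES2.1,chr02,6.68,71.95,79.81,21.15,23.11,11.5,0.29
W4SES,qW4SES3.1,chr03,3.42,112.66,118.05,27.64,28.64,6.0,0.21
W4SES,qW4SES4.1,chr04,3.77,34.42,34.81,15.81,18.24,6.6,0.23
W4SES,qW4SES6.1,chr06,10.5,34.33,37.32,4.13,4.84,17.4,0.36
W4SES,qW4SES8.1,chr08,4.87,77.19,94.96,20.54,24.05,8.5,0.25
W4SES,qW4SES11.1,chr11,8.24,37.06,40.57,6.83,7.63,13.9,0.32
W4SES,qW4SES11.2,chr11,9.43,58.29,66.15,18.70,20.45,11.3,0.29
W4SES,qW4SES11.3,chr11,5.97,81.94,88.01,24.25,25.43,9.2,0.26
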