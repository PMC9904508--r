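chrom,qtl,cm_start,cm_end,mb_start,mb_end,greenhouse.W2SES,greenhouse.W4SES,field.W2SES,field.W4SES,BLUP.W2SES,BLUP.W4SES
chr02,qW2SES2.1/qW4SES2.1,70.60,80.44,20.92,23.44,1,1,1,1,1,1
chr06,qW2SES6.1/qW4SES6.1,31.63,45.10,4.13,4.85,1,1,1,1,1,1
chr08,qW4SES8.1,75.65,96.15,19.81,24.23,0,1,0,1,0,1
chr11,qW2SES11.1/qW4SES11.1,36.36,42.05,6.65,8.34,1,1,1,1,1,1
chr11,qW4SES11.3,80.03,88.01,23.65,25.43,0,1,0,1,0,1
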