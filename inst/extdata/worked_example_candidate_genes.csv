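gene_id,chrom,start,end,qtl
Os02g0568600,chr02,21625022,21625725,qW2SES2.1/qW4SES2.1
Os02g0570400,chr02,21765011,21773418,qW2SES2.1/qW4SES2.1
Os06g0184800,chr06,4264424,4265115,qW2SES6.1/qW4SES6.1
Os06g0184900,chr06,4269116,4270614,qW2SES6.1/qW4SES6.1
Os08g0414700,chr08,19830425,19836080,qW4SES8.1
Os08g0417000,chr08,19950692,19952388,qW4SES8.1
Os08g0417100,chr08,19954825,19956227,qW4SES8.1
Os08g0434300,chr08,21054660,21056008,qW4SES8.1
Os08g0440800,chr08,21445787,21450773,qW4SES8.1
Os08g0450700,chr08,22003703,22006379,qW4SES8.1
Os08g0458200,chr08,22462399,22464860,qW4SES8.1
Os08g0474866,chr08,23403049,23404168,qW4SES8.1
Os08g0480000,chr08,23712632,23717520,qW4SES8.1
Os11g0234200,chr11,7125124,7128857,qW2SES11.1/qW4SES11.1
Os11g0235700,chr11,7221675,7228567,qW2SES11.1/qW4SES11.1
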