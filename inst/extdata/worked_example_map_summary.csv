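chrom,bins_mapped,bins_created,mean_bin_length_kb,lg_length_cm,mean_gap_cm,max_gap_cm
chr01,349,366,118.23,165.63,0.47,2.36
chr02,297,304,118.21,129.40,0.44,1.76
chr03,286,290,125.56,157.38,0.55,3.02
chr04,260,275,129.10,123.20,0.47,2.59
chr05,202,213,140.65,116.44,0.58,2.79
chr06,246,261,119.73,125.74,0.51,4.97
chr07,240,255,116.46,96.62,0.40,2.91
chr08,230,250,113.77,123.04,0.53,3.70
chr09,168,181,127.14,79.51,0.47,4.81
chr10,206,215,107.94,78.82,0.38,1.74
chr11,239,252,115.16,108.19,0.45,2.66
chr12,198,199,138.35,104.08,0.53,5.66
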