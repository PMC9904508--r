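class,parent,bulk
SalOnly_up,1484,1040
NorOnly_down,1772,449
DeltaLFC_gt1,265,8
SalOnly_down,1840,1666
NorOnly_up,1006,438
DeltaLFC_ltm1,498,17
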