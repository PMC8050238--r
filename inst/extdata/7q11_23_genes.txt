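# 7q11.23 Williams-Beuren critical-region gene list (chr7: ~72.4-73.4 Mb), 23 genes
FKBP6
FZD9
BAZ1B
BCL7B
TBL2
MLXIPL
VPS37D
DNAJC30
WBSCR22
STX1A
ABHD11
CLDN3
CLDN4
WBSCR27
WBSCR28
ELN
LIMK1
EIF4H
LAT2
RFC2
CLIP2
GTF2IRD1
GTF2I
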