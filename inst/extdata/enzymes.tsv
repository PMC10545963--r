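name	recognition	cut_offset
XmnI	GAANNNNTTC	5
HpyCH4V	TGCA	2
NsiI	ATGCAT	5
ScaI	AGTACT	3
DraI	TTTAAA	3
FokI	GGATG	14
MnlI	CCTC	11
TaqI	TCGA	1
EcoRI	GAATTC	1
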