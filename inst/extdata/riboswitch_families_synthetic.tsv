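class	family
SAM	SAM
SAM-IV	SAM
SAH	SAM
SAM_alpha	SAM
SAM-I-IV	SAM
SAM-III	SAM
SAM-SAH	SAM
SAM_V	SAM
SAM_VI	SAM
c-di-GMP-I	c-di-GMP
c-di-GMP-II	c-di-GMP
c-di-GMP-I-GGC	c-di-GMP
c-di-GMP-II-GAG	c-di-GMP
c-di-GMP-I-UAU	c-di-GMP
c-di-GMP-II-GCG	c-di-GMP
Guanidine-I	Guanidine
Guanidine-II	Guanidine
Guanidine-III	Guanidine
Guanidine-IV	Guanidine
Cobalamin	Cobalamin
AdoCbl_riboswitch	Cobalamin
AdoCbl-variant	Cobalamin
PreQ1	PreQ1
preQ1-II	PreQ1
preQ1-III	PreQ1
Purine	Purine
2dG-II	Purine
Glycine	Glycine
glycine-GGAnGA	Glycine
M-box	Magnesium
Mg-sensor	Magnesium
T-box	T-box
TPP	TPP
FMN	FMN
Lysine	Lysine
glmS	glmS
THF	THF
Fluoride	Fluoride
Glutamine	Glutamine
ZMP-ZTP	ZMP-ZTP
NiCo	NiCo
yybP-ykoY	Manganese
Moco_RNA_motif	Molybdenum
raiA	raiA
ydaO-yuaA	c-di-AMP
PRPP	PRPP
ppGpp	ppGpp
nadA	NAD
DUF1646	Li-ion
c-AMP-GMP	c-AMP-GMP
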