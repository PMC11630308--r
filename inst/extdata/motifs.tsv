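motif_id	iupac	tf_family
CArG_box	CCWWWWWWGG	MADS
GCC_box	GCCGCC	AP2/ERF
DRE_core	RCCGAC	AP2/ERF
W_box	TTGACY	WRKY
MYB_core	YAACKG	MYB
MYB_AC	ACCWACC	MYB
MBS	CAACTG	MYB
ABRE	ACGTGKC	bZIP
G_box	CACGTG	bZIP
TGA_box	TGACGT	bZIP
NAC_core	CGTRTT	NAC
E_box	CANNTG	bHLH
TCP_site	GGNCCC	TCP
Dof_core	AAAGY	Dof
GATA_box	WGATAR	GATA
HSE	GAANNTTC	HSF
AuxRE	TGTCTC	ARF
SBP_core	GTACR	SPL
CO_like_site	TGTGGT	CO-like
KNOX_site	TGACAGGT	KNOX
RAV1_A	CAACA	RAV
RAV1_B	CACCTG	RAV
SBF_site	GTTAAGTT	SBF
SRS_site	TYTCTC	SRS
TELO_box	AAACCCTA	TRB
SORLIP1	GCCAC	SORLIP
I_box	GATAAG	GATA
CCAAT_box	CCAAT	NF-Y
TATA_box	TATAWAW	GTF
CAAT_box	CAAT	GTF
ARR1_site	NGATT	ARR-B
EIN3_site	AYGWAYCT	EIL
PIF_box	CACGTG	bHLH
LFY_site	CCANTG	LFY
AG_site	TTDCCWWWWNNGG	MADS
WUS_site	TTAATGG	WOX
BPC_site	GAGAGAGA	BPC
TEIL_site	AGCCGCC	EIL
GT1_site	GRWAAW	Trihelix
SEF4_site	RTTTTTR	SEF
P1BS	GNATATNC	PHR1
ARE	AAACCA	ARE
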