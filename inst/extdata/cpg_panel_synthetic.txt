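# Synthetic reconstruction of the 114-gene cancer predisposition
# gene (CPG) panel: genes observed in the printed variant table plus
# representative padding; the published membership is not reproduced.
ALK
APC
ATM
ATR
AXIN2
BAP1
BLM
BMPR1A
BRCA1
BRCA2
BRIP1
BUB1B
CBL
CDC73
CDH1
CDK4
CDKN1B
CDKN1C
CDKN2A
CEBPA
CHEK2
COL7A1
CYLD
DDB2
DICER1
DIS3L2
DKC1
EGFR
EPAS1
ERCC2
ERCC3
ERCC4
ERCC5
EXT1
EXT2
FAH
FANCA
FANCB
FANCC
FANCD2
FANCE
FANCF
FANCG
FANCI
FANCL
FANCM
FH
FLCN
GATA2
GBA1
GJB2
GPC3
HMBS
HNF1A
HRAS
KIT
MAX
MEN1
MET
MITF
MLH1
MRE11
MSH2
MSH6
MUTYH
MYO7A
NBN
NF1
NF2
NSD1
PALB2
PDGFRA
PHOX2B
PMS1
PMS2
POLD1
POLE
POLH
PRKAR1A
PTCH1
PTEN
RAD50
RAD51
RAD51C
RAD51D
RB1
RECQL4
RET
RUNX1
SBDS
SDHA
SDHAF2
SDHB
SDHC
SDHD
SLX4
SMAD4
SMARCA4
SMARCB1
SMARCE1
STK11
SUFU
TERF2IP
TMEM127
TP53
TP53BP1
TSC1
TSC2
VHL
WRN
WT1
XPA
XPC
XRCC2
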