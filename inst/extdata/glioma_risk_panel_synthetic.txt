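# Synthetic reconstruction of the 50-gene glioma-risk panel:
# genes observed in the printed variant table plus representative
# padding; the published membership is not reproduced.
ACD
ADAR
CHD7
CTNND1
DGCR8
DROSHA
EFTUD2
EPCAM
GPR161
GRB2
HERC2
IFIH1
KAT5
KDR
LIG4
MAPK10
MSH5
NAV3
PARK2
PCYT1A
POLQ
POT1
PRKDC
REXO2
RNASEH2A
RNASEH2B
RNASEH2C
RPL5
RTEL1
SAMHD1
SEMA3C
SETD2
SLC25A13
SLC4A7
SPAG1
SSPO
STAG2
TERF1
TERF2
TFAP2E
TGFBR2
TINF2
TLR4
TREX1
TRPM1
TYK2
UNC13B
WDR7
ZMYND11
ZNF544
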