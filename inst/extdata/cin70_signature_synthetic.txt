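# CIN70 chromosomal-instability expression signature (70 genes).
# Transcribed from the published signature literature using current HGNC
# symbols; treat as a synthetic stand-in and override with read_signature()
# if you need the authoritative list.
TPX2
PRC1
FOXM1
CDK1
TGIF2
MCM2
H2AFZ
TOP2A
PCNA
UBE2C
MELK
TRIP13
NCAPD2
MCM7
RNASEH2A
RAD51AP1
KIF20A
CDC45
MAD2L1
ESPL1
CCNB2
FEN1
TTK
CCT5
RFC4
ATAD2
CKAP5
NUP205
CDC20
CKS2
RRM2
ELAVL1
CCNB1
RRM1
AURKB
MSH6
EZH2
CTPS1
DKC1
OIP5
CDCA8
PTTG1
CEP55
H2AFX
CMAS
NCAPH
MCM10
LSM4
NCAPG2
ASF1B
ZWINT
PBK
ZWILCH
CDCA3
ECT2
CDC6
UNG
MTCH2
RAD21
ACTL6A
GPI
SRSF2
HDGF
NXT1
NEK2
DHCR7
AURKA
NDUFAB1
KIF4A
SMC4
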