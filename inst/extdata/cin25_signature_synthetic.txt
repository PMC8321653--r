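# CIN25 chromosomal-instability expression signature (25 genes).
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
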