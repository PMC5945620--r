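# Driver gene list (editable). Default set: well-established cancer
# driver genes from the consensus literature; replace with your own
# list (one symbol per line) as needed.
ABL1
AKT1
APC
ARID1A
ATM
BRAF
BRCA1
BRCA2
CDH1
CDKN2A
CTNNB1
EGFR
ERBB2
EZH2
FBXW7
FGFR2
FGFR3
GNAS
HRAS
IDH1
IDH2
KIT
KRAS
MET
MLH1
MSH2
MSH6
NF1
NOTCH1
NRAS
PDGFRA
PIK3CA
PIK3R1
POLE
PTCH1
PTEN
RB1
RET
SETD2
SF3B1
SMAD4
SMARCA4
SMO
STK11
TP53
VHL
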