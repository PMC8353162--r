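gene	term
SOX2	GO:0003700
LMX1A	GO:0003700
MSX1	GO:0003700
ATOH1	GO:0003700
OLIG3	GO:0003700
PAX3	GO:0003700
PAX7	GO:0003700
NEUROG1	GO:0003700
ASCL1	GO:0003700
GSX1	GO:0003700
GSX2	GO:0003700
DBX1	GO:0003700
DBX2	GO:0003700
PAX6	GO:0003700
PRDM12	GO:0003700
NKX6-1	GO:0003700
NKX6-2	GO:0003700
IRX3	GO:0003700
FOXN4	GO:0003700
OLIG2	GO:0003700
NKX2-2	GO:0003700
FOXA2	GO:0003700
ARX	GO:0003700
LHX2	GO:0003700
LHX9	GO:0003700
FOXD3	GO:0003700
POU4F1	GO:0003700
LHX1	GO:0003700
ISL1	GO:0003700
TLX3	GO:0003700
PHOX2B	GO:0003700
MNX1	GO:0003700
LBX1	GO:0003700
PAX2	GO:0003700
LMX1B	GO:0003700
DMRT3	GO:0003700
WT1	GO:0003700
EVX1	GO:0003700
EVX2	GO:0003700
EN1	GO:0003700
FOXP2	GO:0003700
VSX2	GO:0003700
SOX14	GO:0003700
LHX3	GO:0003700
TBX2	GO:0003700
TBX3	GO:0003700
SIM1	GO:0003700
SOX10	GO:0003700
TFAP2A	GO:0003700
NEUROG2	GO:0003700
NEUROD1	GO:0003700
SIX1	GO:0003700
RUNX3	GO:0003700
RUNX1	GO:0003700
MAF	GO:0003700
SOX9	GO:0003700
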