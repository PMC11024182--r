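gene	earliest_ps
CAMK1	1
EEF2	1
GNAI1	1
HRAS	1
KRAS	1
NRAS	1
PPP1CA	1
PPP1CB	1
PPP1CC	1
PRKAA1	1
PRKAA2	1
RHOA	1
CALM1	2
CALM2	2
CALM3	2
MAP2K1	2
MAP2K2	2
MAPK1	2
MAPK3	2
PIK3CA	2
PIK3CB	2
PPP3CA	2
PPP3CB	2
PPP3CC	2
PPP3R1	2
ROCK1	2
SRC	2
PRKAG1	3
CAMK2A	4
CAMK2B	4
CAMK4	4
CAMKK1	4
CAMKK2	4
GNAQ	4
PRKACA	4
PRKACB	4
ROCK2	4
ITPR1	5
ITPR2	5
CCND1	6
GNAS	6
ITPR3	6
CACNB1	7
CACNB2	7
CACNB3	7
CACNB4	7
CAMK2D	7
CAMK2G	7
MYLK	7
PLCB4	7
ADCY5	8
ADCY6	8
PTGS2	8
KCNJ6	9
RYR1	10
RYR2	10
ADCY9	11
GUCY1A2	11
OXTR	11
PIK3R5	11
PLA2G4A	11
ADCY1	12
ADCY2	12
ADCY7	12
ADCY8	12
CACNA2D1	12
CACNA2D3	12
CACNA2D4	12
CACNG1	12
CACNG3	12
CACNG4	12
CACNG5	12
CD38	12
EEF2K	12
EGFR	12
ELK1	12
FOS	12
JUN	12
KCNJ12	12
KCNJ2	12
KCNJ3	12
KCNJ4	12
KCNJ5	12
MEF2C	12
MYLK3	12
NFATC1	12
NFATC2	12
NFATC3	12
OXT	12
PLA2G4F	12
PLCB1	12
PPP1R12A	12
PRKAB1	12
RAF1	12
RYR3	12
ADCY3	13
ADCY4	13
CACNA1C	13
CACNA1D	13
CACNA1F	13
CACNA1S	13
CACNA2D2	13
CACNG2	13
MYLK2	13
PLA2G4B	13
PLCB2	13
PLCB3	13
CACNG6	14
CACNG7	14
CACNG8	14
CDKN1A	14
ELK4	14
FOSB	14
JUNB	14
JUND	14
MEF2A	14
MEF2B	14
MEF2D	14
MYL6	14
NFATC4	14
NOS3	14
NPR1	14
NPR2	14
PLA2G4C	14
PLA2G4D	14
PLA2G4E	14
RGS2	14
PIK3R1	15
PIK3R2	15
PIK3R3	15
PRKAB2	15
PRKAG2	15
PRKAG3	15
PRKAR1A	15
PRKAR1B	15
PRKAR2A	15
PRKAR2B	15
ACTB	16
ACTG1	16
MYL9	16
PIK3CD	16
PIK3CG	16
PIK3R6	16
PPP1R12B	16
PPP1R12C	16
GUCY1A1	17
TRPM2	17
GUCY1B1	19
KCNJ11	19
KCNJ15	19
MAP2K5	19
MAPK7	19
CALML6	20
MYL6B	20
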