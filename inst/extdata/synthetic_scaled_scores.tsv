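gene	species_id	scaled_score
ADCY1	csavignyi	0.1549946
ADCY6	csavignyi	0.1291254
ADCY8	csavignyi	0.1283391
CACNA2D3	csavignyi	0.1678682
CACNB1	csavignyi	0.2330657
CACNG4	csavignyi	0.1129719
CALM3	csavignyi	0.1504715
CAMK2A	csavignyi	0.2808750
CAMK2B	csavignyi	0.2795450
CAMK2D	csavignyi	0.2450659
CAMKK2	csavignyi	0.1728819
CCND1	csavignyi	0.2056403
EEF2	csavignyi	0.2468443
EEF2K	csavignyi	0.2243776
ELK1	csavignyi	0.2256531
FOS	csavignyi	0.1520173
GNAI1	csavignyi	0.1519110
GNAQ	csavignyi	0.1829390
GNAS	csavignyi	0.2825709
GUCY1A2	csavignyi	0.2861983
HRAS	csavignyi	0.2461029
ITPR1	csavignyi	0.2449132
ITPR2	csavignyi	0.2093659
ITPR3	csavignyi	0.1133380
JUN	csavignyi	0.2225376
KCNJ12	csavignyi	0.2635532
KCNJ2	csavignyi	0.2482030
KCNJ5	csavignyi	0.1944206
KCNJ6	csavignyi	0.2093711
KRAS	csavignyi	0.2096567
MAPK1	csavignyi	0.1131775
MEF2C	csavignyi	0.1769488
MYLK	csavignyi	0.2231129
NFATC3	csavignyi	0.2621385
NRAS	csavignyi	0.1771389
PIK3CA	csavignyi	0.1868432
PIK3CB	csavignyi	0.2161546
PLA2G4F	csavignyi	0.2190710
PLCB1	csavignyi	0.2424672
PLCB4	csavignyi	0.1840240
PPP1CB	csavignyi	0.2783856
PPP1CC	csavignyi	0.2861916
PPP1R12A	csavignyi	0.1549631
PPP3CA	csavignyi	0.2433385
PPP3CB	csavignyi	0.2755831
PPP3CC	csavignyi	0.2215542
PPP3R1	csavignyi	0.2266002
PRKAA1	csavignyi	0.2816584
PRKACA	csavignyi	0.2660158
PRKACB	csavignyi	0.2172967
PTGS2	csavignyi	0.2607816
RHOA	csavignyi	0.1333982
ROCK1	csavignyi	0.2505403
ROCK2	csavignyi	0.2251793
RYR2	csavignyi	0.1396493
RYR3	csavignyi	0.1273765
SRC	csavignyi	0.1964614
ADCY1	cintestinalis	0.1486776
ADCY2	cintestinalis	0.2095580
ADCY5	cintestinalis	0.1973830
ADCY6	cintestinalis	0.1393309
ADCY8	cintestinalis	0.1375505
ADCY9	cintestinalis	0.2004954
CACNB1	cintestinalis	0.2799280
CACNB2	cintestinalis	0.1707879
CACNG1	cintestinalis	0.1445445
CALM2	cintestinalis	0.1591752
CALM3	cintestinalis	0.2061602
CAMK1	cintestinalis	0.1144873
CAMK2A	cintestinalis	0.2544032
CAMK2D	cintestinalis	0.1304866
CAMK2G	cintestinalis	0.2077900
CAMK4	cintestinalis	0.2134484
CAMKK1	cintestinalis	0.2220376
CAMKK2	cintestinalis	0.2393000
CD38	cintestinalis	0.1328204
EEF2	cintestinalis	0.1666152
EEF2K	cintestinalis	0.2808593
EGFR	cintestinalis	0.2006308
ELK1	cintestinalis	0.1349678
FOS	cintestinalis	0.2670927
GNAQ	cintestinalis	0.1475352
GNAS	cintestinalis	0.2771346
ITPR1	cintestinalis	0.2702419
ITPR3	cintestinalis	0.1351595
JUN	cintestinalis	0.2519892
KCNJ12	cintestinalis	0.1922209
KCNJ2	cintestinalis	0.1350599
KCNJ3	cintestinalis	0.2699661
KCNJ4	cintestinalis	0.1712347
KCNJ5	cintestinalis	0.1680956
KRAS	cintestinalis	0.1833072
MAP2K1	cintestinalis	0.1968602
MAP2K2	cintestinalis	0.1768486
MYLK	cintestinalis	0.1944506
MYLK3	cintestinalis	0.1196069
NFATC2	cintestinalis	0.1443505
NFATC3	cintestinalis	0.2875050
NRAS	cintestinalis	0.1697156
OXT	cintestinalis	0.1414057
OXTR	cintestinalis	0.1985122
PIK3R5	cintestinalis	0.1139900
PLA2G4A	cintestinalis	0.1717336
PLA2G4F	cintestinalis	0.1159657
PLCB1	cintestinalis	0.2667275
PLCB4	cintestinalis	0.2423337
PPP3CC	cintestinalis	0.1673732
PPP3R1	cintestinalis	0.1801880
PRKAA1	cintestinalis	0.1704666
PRKAB1	cintestinalis	0.1267863
PRKACA	cintestinalis	0.2468963
PRKAG1	cintestinalis	0.2191606
RAF1	cintestinalis	0.1367983
RHOA	cintestinalis	0.1164794
ROCK1	cintestinalis	0.1977046
ROCK2	cintestinalis	0.1906488
RYR1	cintestinalis	0.1214957
RYR2	cintestinalis	0.1695774
RYR3	cintestinalis	0.2687435
SRC	cintestinalis	0.2781352
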