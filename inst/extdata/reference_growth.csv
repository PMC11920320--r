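cell_line,tier,alpha,beta,r_squared_pct
HOS,High,2.1797,0.5300,99.79
OHS,High,1.1640,0.6696,99.00
OSA,High,1.1353,0.7198,99.61
HOS-143B,High,0.8803,0.8649,99.99
HOS-MNNG,High,0.8598,0.8555,99.99
MHM,High,0.8137,0.8633,99.99
HAL,Medium high,0.4663,0.8530,98.92
IOR/OS9,Medium high,0.4351,0.8134,99.09
ZK-58,Medium high,0.3742,0.8781,99.80
Cal-72,Medium high,0.3021,0.8562,99.67
Saos-2,Medium,0.2573,0.7161,99.38
G-292,Medium,0.2016,0.8619,99.14
KPD,Medium,0.1668,0.8704,99.82
IOR/OS14,Medium,0.1576,0.7687,96.66
IOR/OS15,Low,0.1251,0.6742,99.69
U2OS,Low,0.1000,0.8419,99.15
MG-63,Low,0.0801,0.8377,99.53
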