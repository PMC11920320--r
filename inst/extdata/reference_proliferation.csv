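cell_line,tier,rho5,n5,r2_5_pct,rho10,n10,r2_10_pct,weighted_average
OSA,High,1.77,4,93.57,2.88,2,97.33,2.14
MHM,High,1.75,3,96.81,2.54,2,98.08,2.07
U2OS,High,1.92,4,98.92,2.16,2,98.78,2.00
HOS-143B,High,1.77,6,97.52,1.97,3,95.11,1.84
IOR/OS15,High,1.59,2,99.20,1.89,2,96.61,1.74
Cal-72,Medium high,1.45,3,98.44,1.67,2,97.13,1.54
IOR/OS18,Medium high,1.52,4,96.93,1.54,2,96.98,1.53
IOR/OS10,Medium high,1.48,6,97.38,1.65,2,97.88,1.53
HOS,Medium high,1.48,8,95.57,1.58,2,95.76,1.50
OHS,Medium high,1.44,7,99.63,1.60,3,99.68,1.49
IOR/SARG,Medium,1.32,3,99.57,1.65,3,99.70,1.48
MG-63,Medium,1.50,8,92.35,1.43,3,91.99,1.48
Saos-2,Medium,1.25,4,97.64,1.86,2,97.05,1.45
HOS-MNNG,Medium,1.37,6,98.04,1.43,3,97.19,1.39
ZK-58,Medium,1.17,2,98.56,1.36,2,97.59,1.26
IOR/OS14,Low,1.02,3,95.23,1.15,3,90.99,1.09
HAL,Low,0.87,4,99.12,1.22,4,99.61,1.05
IOR/OS9,Low,0.93,6,99.36,1.29,2,99.30,1.02
KPD,Low,0.88,6,99.74,1.00,3,99.42,0.92
IOR/MOS,Low,0.78,2,99.64,1.04,2,98.65,0.91
G-292,Low,0.37,4,95.71,0.43,2,93.50,0.39
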