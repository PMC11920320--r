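cell_line,alpha,beta,rho,D_bar,TL,CL,IL,ML,PL
HOS,2.1797,0.5300,1.50,1.19e-2,4,508,1294,2406,3
OSA,1.1353,0.7198,2.14,9.26e-3,4,465,678,2470,3
HOS-143B,0.8803,0.8649,1.84,8.35e-3,4,376,1010,2048,3
HOS-MNNG,0.8598,0.8555,1.39,1.03e-2,4,590,887,1513,2
MHM,0.8137,0.8633,2.07,5.92e-3,4,177,580,888,3
OHS,1.1640,0.6696,1.49,9.67e-3,4,561,95,299,2
Cal-72,0.3021,0.8562,1.54,3.95e-3,3,230,41,246,2
HAL,0.4663,0.8530,1.05,5.96e-3,3,310,45,1863,1
IOR/OS9,0.4351,0.8134,1.02,2.88e-3,3,910,83,47,1
ZK-58,0.3742,0.8781,1.26,1.66e-3,3,24,12,7,2
KPD,0.1668,0.8704,0.92,3.33e-3,2,240,90,291,1
G-292,0.2016,0.8619,0.39,2.99e-3,2,242,32,156,1
Saos-2,0.2573,0.7161,1.45,9.39e-4,2,52,109,697,2
IOR/OS14,0.1576,0.7687,1.09,5.55e-4,2,8,109,507,2
MG-63,0.0801,0.8377,1.48,5.01e-5,1,6,95,231,3
IOR/OS15,0.1251,0.6742,1.74,1.78e-4,1,94,467,931,3
U2OS,0.1000,0.8419,2.00,1.34e-4,1,19,771,2039,3
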