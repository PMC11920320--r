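cell_line,tier,t_first_days,t_last_days,D_bar,sd,cv_pct
HOS,High,11,28,1.19e-2,2.37e-3,20
HOS-MNNG,High,8,21,1.03e-2,3.92e-3,38
OHS,High,3,28,9.67e-3,7.44e-4,8
OSA,High,7,22,9.26e-3,9.88e-4,11
HOS-143B,High,8,21,8.35e-3,3.55e-3,42
HAL,Medium high,7,28,5.96e-3,3.15e-3,53
MHM,Medium high,4,24,5.92e-3,2.68e-3,45
Cal-72,Medium high,7,34,3.95e-3,1.22e-3,31
KPD,Medium high,7,55,3.33e-3,9.31e-4,28
G-292,Medium high,18,69,2.99e-3,1.33e-3,44
IOR/OS9,Medium high,16,48,2.88e-3,1.89e-3,66
ZK-58,Medium high,7,45,1.66e-3,4.54e-4,27
Saos-2,Medium,15,90,9.39e-4,7.30e-5,8
IOR/OS14,Medium,13,116,5.55e-4,1.78e-4,32
IOR/OS15,Low,11,129,1.78e-4,4.41e-5,25
U2OS,Low,36,129,1.34e-4,4.85e-5,36
MG-63,Low,23,172,5.01e-5,1.57e-5,31
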