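indicator,y1990,y1995,y2000,y2005,y2010,y2015
PD,0.1568,0.1554,0.1540,0.1526,0.1547,0.1539
LFI,0.0833,0.0839,0.0827,0.0825,0.0813,0.0813
NDVI,0.0387,0.0280,0.0000,0.0266,0.0280,0.1028
LDI,0.0750,0.0755,0.0753,0.0758,0.0769,0.0788
APAI,0.0116,0.0118,0.0111,0.0110,0.0106,0.0101
ESV,0.1252,0.1293,0.1257,0.1274,0.1289,0.1289
ER,0.0696,0.0704,0.0700,0.0706,0.0715,0.0730
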