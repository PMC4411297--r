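gene	position	change	mep_normoxia	mep_hypoxia	m2	m1
AP2A1	19:50295238	C520T, R174X	0	15.5	NA	NA
APP	21:27326988	C1546T, R516C	0	8.5	NA	NA
ASCC2	22:30221126	C202T, R68X	0.9	19.1	NA	NA
C1QA	1:22965523	C361T, R121W	NA	NA	0.1	10.7
CAST	5:96106257	C1826T, S609F	0	7.2	0.1	5.2
CCDC109B	4:110605624	C638T, S213L	0.3	20.4	NA	NA
EVI2B	17:29632509	C119T, S40L	0	18.1	0.6	12.1
FAM89B	11:65340979	C437T, P146L	0	16.2	NA	NA
GLTSCR2	19:48253494	C349T, R117W	0.5	6.8	0.2	11.2
GPR160	3:169801777	C17T, S6L	0.6	15.7	NA	NA
HLA-DMA	6:32918428	C241T, R81C	0.6	9.9	NA	NA
ICAM3	19:10444896	C1381T, Q461X	0	18.4	0	7.2
ITGB2	21:46319067	C908T, S303L	0.9	5.1	NA	NA
LGALS9	17:25967659	C193T, R65W	0.2	7.6	0	5.4
LRP10	14:23346296	C1702T, R568X	0	6.2	NA	NA
NBN	8:90955531	C2134T, H712Y	4	24.2	0	22.4
PABPC4	1:40027426	C1840T, H614Y	4.4	31.7	1.6	39.9
PCGF3	4:737366	C367T, R123W	2	22.2	0	12.8
PPA2	4:106317458	C319T, Q107X	NA	NA	0.2	8.8
PRPF40A	2:153515789	C2404T, R802X	0	5.1	NA	NA
RGS10	10:121275109	C311T, S104L	0.2	7.9	0	15.3
RNH1	11:499165	C464T, S155L	3	18.5	0	9.2
SDHB	1:17371320	C136T, R46X	2.6	23	1.1	15.6
SIN3A	15:75668008	C3589T, Q1197X	0	17.2	NA	NA
SETX	9:135201977	C5008T, Q1670X	1.9	24.6	NA	NA
SUPT6H	17:27005584	C1138T, R380X	0.6	12.3	NA	NA
TMEM109	11:60687274	C109T, R37X	0	11.2	NA	NA
TMEM131	2:98409343	C3650T, S1217L	5.7	26.4	NA	NA
TMEM179B	11:62556843	C364T, R122X	NA	NA	0	5.2
TRAPPC11	4:184585120	C100T, R34X	0	15.8	NA	NA
UBE2J1	6:90048208	C292T, H98Y	4	16.1	1.1	18.9
VIM	10:17277300	C1141T, R381C	0.3	15.7	NA	NA
XPO1	2:61760990	C43T, Q15X	2.7	10	NA	NA
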