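gene	ref	msn	yak
HXK1	459	77	228
HSP104	327	121	229
MSC1	629	58	296
SOL4	148	28	107
YKL187c	321	28	124
GLC3	390	96	425
GLK1	852	465	889
GPX1	271	41	196
GSY2	184	45	245
HSP12	3790	807	2436
HPF1	650	137	611
NCA3	744	134	683
SOD1	1964	841	1558
STF2	838	183	1004
TPS1	569	245	612
TSL1	274	45	245
ATF2	31	33	173
PRM5	116	339	164
SSA2	997	1519	611
DAL3	198	403	58
FSH1	220	271	68
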