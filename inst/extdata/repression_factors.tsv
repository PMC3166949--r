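gene	strain	short_factor	growth_factor
TPS1	REF_PKA_PLUS	7.7	1.3
TPS2	REF_PKA_PLUS	7.1	1.6
HXT6/7	REF_PKA_PLUS	30	68
GRX2	REF_PKA_PLUS	9.5	2.9
PEP4	REF_PKA_PLUS	15	1.8
TPS1	TPK_NULL_MSN	1.3	1.5
TPS2	TPK_NULL_MSN	1.1	1.1
HXT6/7	TPK_NULL_MSN	0.2	0.2
GRX2	TPK_NULL_MSN	0.7	0.9
PEP4	TPK_NULL_MSN	0.4	1
TPS1	TPK_NULL_YAK	1.1	0.3
TPS2	TPK_NULL_YAK	1.3	0.4
HXT6/7	TPK_NULL_YAK	1.4	0.3
GRX2	TPK_NULL_YAK	1.4	0.5
PEP4	TPK_NULL_YAK	1.2	0.6
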