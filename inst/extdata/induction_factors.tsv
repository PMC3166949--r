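gene	strain	short_factor	growth_factor
PDC1	REF_PKA_PLUS	12.8	27
PDC5	REF_PKA_PLUS	235	1.3
ALD5	REF_PKA_PLUS	5	3
TMT1	REF_PKA_PLUS	9.7	2
YMC2	REF_PKA_PLUS	11	4
ATR1	REF_PKA_PLUS	13.8	2.3
PDC1	TPK_NULL_MSN	15	21
PDC5	TPK_NULL_MSN	70	4.3
ALD5	TPK_NULL_MSN	3.4	3.2
TMT1	TPK_NULL_MSN	1.7	1.9
YMC2	TPK_NULL_MSN	2.2	1.9
ATR1	TPK_NULL_MSN	2.6	2.9
PDC1	TPK_NULL_YAK	1.2	4.4
PDC5	TPK_NULL_YAK	1.8	2
ALD5	TPK_NULL_YAK	0.9	0.6
TMT1	TPK_NULL_YAK	1.1	0.7
YMC2	TPK_NULL_YAK	0.8	0.7
ATR1	TPK_NULL_YAK	1.4	0.9
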