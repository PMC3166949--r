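class	direction	ref	pka_null	pka_activated	genes
1	INDUCTION	+	+	-	PFK1,ENO2
1	REPRESSION	+	+	-	CRC1,PCK1,MLS1
2	INDUCTION	+	-	+	ARG3,THR4
2	REPRESSION	+	-	+	GRX2,PEP4
3	INDUCTION	+	+	+	HXT3,RPL7A,HOR2
3	REPRESSION	+	+	+	ACS1,ADY2,CIT3
4	INDUCTION	+	-	-	SDT1,STR3
4	REPRESSION	+	-	-	HXT6,MDH1
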