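gene	ref_ethanol	ref_glucose	msn_ethanol	msn_glucose	yak_ethanol	yak_glucose
GPX1	100	6	15	8	73	45
GSY2	100	13	23	15	80	62
HPF1	100	41	21	42	94	108
MSC1	100	4	9	6	45	39
TSL1	100	8	16	9	90	92
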