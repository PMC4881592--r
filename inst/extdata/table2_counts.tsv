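disease	A	B	C	D	sensitivity	specificity
Colon	42	21	19	10	0.476	0.429
Pancreatic	54	29	33	17	0.586	0.64
Prostate	24	2	14	1	0.5	0.591
Lung	41	34	25	20	0.588	0.714
Breast	49	42	29	26	0.619	0.429
Bladder	70	34	42	17	0.5	0.694
Kidney	37	10	21	6	0.6	0.556
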