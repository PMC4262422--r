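# Published percent-identity matrix of aligned group 1 allergen
# preproenzymes from eight mite species (lower triangle as printed;
# symmetric completion).
taxon	DerF1	DerP1	EurM1	PsoO1	SarS1	AcaS1	BloT1	TyrP1
DerF1	100.00	83.01	86.58	64.86	44.98	35.67	35.41	32.01
DerP1	83.01	100.00	84.59	62.58	44.90	33.00	34.19	29.97
EurM1	86.58	84.59	100.00	64.49	44.30	35.29	37.38	30.65
PsoO1	64.86	62.58	64.49	100.00	43.85	35.95	33.87	30.00
SarS1	44.98	44.90	44.30	43.85	100.00	27.30	30.97	27.42
AcaS1	35.67	33.00	35.29	35.95	27.30	100.00	42.37	39.38
BloT1	35.41	34.19	37.38	33.87	30.97	42.37	100.00	38.23
TyrP1	32.01	29.97	30.65	30.00	27.42	39.38	38.23	100.00
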