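# Residue states of eight mite group 1 allergens at the 14 positions of the
# cross-reactive 4C1 monoclonal-antibody epitope (Der f 1 mature
# coordinates). '-' marks an alignment gap in that species.
taxon	14	16	18	19	21	156	157	159	181	182	186	199	202	204
DerF1	E	D	R	S	R	G	R	I	T	Q	Y	D	Y	Y
DerP1	E	D	R	Q	R	G	R	I	A	Q	Y	D	Y	Y
EurM1	E	D	R	S	R	G	R	I	T	Q	Y	D	Y	Y
PsoO1	E	D	R	A	G	G	R	I	K	Q	Y	D	Y	Y
SarS1	E	D	R	K	G	G	K	V	K	Y	V	D	Y	Y
AcaS1	T	D	R	-	S	G	G	I	E	N	Y	E	Y	K
BloT1	N	D	R	Q	A	S	G	L	T	V	Y	N	Y	Y
TyrP1	S	D	R	N	I	N	G	M	D	S	Y	E	Y	R
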