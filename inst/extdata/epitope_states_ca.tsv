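# Residue states at the 4 positions of the calcium-binding epitope
# (Der f 1 mature coordinates).
taxon	57	58	60	92
DerF1	D	L	E	E
DerP1	D	L	E	E
EurM1	D	L	E	E
PsoO1	D	L	E	E
SarS1	G	L	E	S
AcaS1	R	L	K	E
BloT1	E	L	E	E
TyrP1	H	L	R	D
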