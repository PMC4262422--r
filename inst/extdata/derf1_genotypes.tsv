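# Curated genotype table: 22 direct-sequenced D. farinae group 1 allergen
# amplicons (16 Pakistan, 6 USA). Columns are gene-alignment nt coordinates
# (position 1 = first nt of the start codon, introns counted). Codon-valued
# columns are exonic, single-base columns intronic; '-' = site does not vary
# in this species (read as NA). IUPAC letters mark heterozygous sites.
individual	locality	113	152	312	589	600	680	686	718	794	824	829	842	843	935	971	978	996	1011	1014	1052	1207	1211	1268
RS17	PK	-	A	-	-	ACG	G	T	C	CGA	-	-	C	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS20	PK	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS25	PK	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS26	PK	-	W	-	-	ACK	G	Y	M	CGA	-	-	C	G	-	-	ATT	ATY	-	TTY	T	ACW	TGG	-
RS27	PK	-	T	-	-	ACT	G	C	A	CGA	-	-	C	T	-	-	ATT	ATC	-	TTC	T	ACA	TGG	-
RS29	PK	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS30	PK	-	T	-	-	ACT	G	C	A	CGA	-	-	C	T	-	-	ATT	ATC	-	TTC	T	ACA	TGG	-
RS31	PK	-	T	-	-	ACT	G	C	A	CGA	-	-	C	T	-	-	ATC	ATC	-	TTC	T	ACA	CGG	-
RS33	PK	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS34	PK	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS35	PK	-	T	-	-	ACT	G	C	A	CGA	-	-	C	T	-	-	ATT	ATC	-	TTC	T	ACA	TGG	-
RS36	PK	-	T	-	-	ACT	G	C	A	CGA	-	-	C	T	-	-	ATT	ATC	-	TTC	T	ACA	TGG	-
RS37	PK	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS40	PK	-	T	-	-	ACK	G	C	M	CGA	-	-	C	K	-	-	ATT	ATY	-	TTY	T	ACW	TGG	-
RS41	PK	-	A	-	-	ACG	G	T	C	AGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS42	PK	-	A	-	-	ACG	R	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTC	A	ACT	TGG	-
RS03	USA	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS59	USA	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS60	USA	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS61	USA	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS62	USA	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
RS63	USA	-	A	-	-	ACG	G	T	C	CGA	-	-	T	G	-	-	ATT	ATT	-	TTT	T	ACT	TGG	-
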