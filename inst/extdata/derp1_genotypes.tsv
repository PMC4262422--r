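# Curated genotype table: 12 direct-sequenced D. pteronyssinus group 1
# allergen amplicons (8 Pakistan, 4 USA). Same conventions as the
# D. farinae table; columns 680/686/718 fall in the intron that is absent
# from this species and are '-' throughout.
individual	locality	113	152	312	589	600	680	686	718	794	824	829	842	843	935	971	978	996	1011	1014	1052	1207	1211	1268
RS12	PK	T	-	G	TAC	-	-	-	-	-	C	A	-	-	GCA	AGC	-	-	GCA	-	-	-	-	GAA
RS16	PK	T	-	G	TAC	-	-	-	-	-	C	A	-	-	GTA	AGC	-	-	GCA	-	-	-	-	GAA
RS18	PK	T	-	G	TAC	-	-	-	-	-	C	A	-	-	GTA	AGC	-	-	GCA	-	-	-	-	GAA
RS19	PK	C	-	R	TAC	-	-	-	-	-	C	R	-	-	GCA	AGC	-	-	GCW	-	-	-	-	GAA
RS24	PK	T	-	G	TAC	-	-	-	-	-	C	A	-	-	GCA	AGC	-	-	GCA	-	-	-	-	GAA
RS65	PK	T	-	G	TAC	-	-	-	-	-	C	A	-	-	GTA	AGC	-	-	GCA	-	-	-	-	GAA
RS68	PK	T	-	G	TAC	-	-	-	-	-	C	A	-	-	GYA	AGC	-	-	GCA	-	-	-	-	GAA
RS73	PK	T	-	G	TAC	-	-	-	-	-	C	A	-	-	GYA	AGC	-	-	GCA	-	-	-	-	GAA
RS6	USA	T	-	G	TAC	-	-	-	-	-	C	R	-	-	GCA	AGC	-	-	GCA	-	-	-	-	GAA
RS45	USA	T	-	G	TAC	-	-	-	-	-	C	A	-	-	GCA	AGC	-	-	GCA	-	-	-	-	GAA
RS51	USA	T	-	G	CAC	-	-	-	-	-	T	A	-	-	GCA	ACC	-	-	GCT	-	-	-	-	CAA
RS52	USA	T	-	G	TAC	-	-	-	-	-	C	A	-	-	GCA	AGC	-	-	GCA	-	-	-	-	GAA
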