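position	ref	alt	gene	aa_difference	detected_before
1788	C	T	rnl	N/A	yes
2091	A	G	rnl	N/A	yes
2364	C	CC	rnl	N/A	no
4102	C	G	rns	N/A	yes
4463	C	A	rns	N/A	yes
4525	AC	A	rns	N/A	no
4777	AA	A	Intergenic	N/A	no
6906	A	T	cox1-I2b	S21C	yes
8376	C	CTAC	cox1	An extra Y residue after Y400	no
8529	G	T	cox1	E451D	yes
10309	TC	CT	cob	I46T	yes
11218	T	A	cob-I1	I121N	yes
11644	A	C	cob-I1	H263P	yes
13196	C	T	cob-I1	Synonymous	yes
13751	C	T	cob	Synonymous	yes
15081	TA	T	atp6	L109F and R111G	yes
15088	G	GA	atp6	L109F and R111G	yes
15200	G	T	atp6	V149F	yes
18648	G	A	cox2	V30I	yes
19152	A	G	cox2	S198G	yes
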