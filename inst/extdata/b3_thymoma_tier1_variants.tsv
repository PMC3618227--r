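gene	chrom	pos	ref	alt	effect	label
BCOR	chrX	39930263	-	TC	frameshift	L1067fs
FBN3	chr19	8162193	CTG	-	inframe_indel	S1756del
LDB3	chr10	88476529	G	T	splice_site	
PCNXL3	chr11	65385813	C	A	non_synonymous	P327Q
PHF15	chr5	133914340	T	A	non_synonymous	L569Q
PION	chr7	76978720	T	C	non_synonymous	E498G
PPP1R3A	chr7	113517959	C	G	non_synonymous	G1063A
SFXN3	chr10	102795325	T	C	non_synonymous	F82S
SRGAP1	chr12	64491096	G	A	non_synonymous	R585H
TAF1	chrX	70627923	C	T	non_synonymous	R1435C
VN1R5	chr1	247419950	C	T	non_synonymous	R193W
WDR70	chr5	37727093	G	A	non_synonymous	R608H
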