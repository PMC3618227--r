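gene	chrom	pos	mutant	total
BCOR	chrX	39930263	90	100
FBN3	chr19	8162193	67	100
LDB3	chr10	88476529	0	0
PCNXL3	chr11	65385813	42	100
PHF15	chr5	133914340	59	100
PION	chr7	76978720	0	100
PPP1R3A	chr7	113517959	0	0
SFXN3	chr10	102795325	14	100
SRGAP1	chr12	64491096	27	100
TAF1	chrX	70627923	0	100
VN1R5	chr1	247419950	50	100
WDR70	chr5	37727093	34	100
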