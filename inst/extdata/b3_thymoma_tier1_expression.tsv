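gene	fpkm	ci_low	ci_high	mutant_pct
BCOR	18.87	0.00	836.48	90
FBN3	1.66	1.53	1.79	67
LDB3	0.00	0.00	0.00	NA
PCNXL3	18.96	18.33	19.59	42
PHF15	37.99	0.00	214.34	59
PION	15.68	0.00	140.89	0
PPP1R3A	0.00	0.00	0.01	NA
SFXN3	6.01	0.00	13.42	14
SRGAP1	1.29	0.00	27.89	27
TAF1	12.22	0.00	64.17	0
VN1R5	0.03	0.00	0.06	50
WDR70	25.67	24.21	27.13	34
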