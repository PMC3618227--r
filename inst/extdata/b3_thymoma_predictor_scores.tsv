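gene	sift_pred	sift_score	polyphen_pred	polyphen_score
PCNXL3	Tolerated	0.57	Damaging	0.998
PHF15	Tolerated	0.59	Damaging	1
PION	Tolerated	0.1	Damaging	0.974
PPP1R3A	Tolerated	0.24	Tolerated	0.001
SFXN3	Damaging	0	Damaging	0.996
SRGAP1	Damaging	0	Damaging	1
TAF1	Damaging	0	Damaging	1
VN1R5	-	-	Damaging	0.986
WDR70	Damaging	0	Damaging	1
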