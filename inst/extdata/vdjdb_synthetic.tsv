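cdr3	v.segm	j.segm	antigen.epitope	antigen.species
CRLIRVATGSPQHPAKKF	TRBV20-1*01		NLVPMVATV	CMV
CVYRKSGQAAGYRECVIF	TRBV30-1*01		KAFSPEVIPMF	HIV-1
CRLIRVATGSPQHPAKKF	TRBV20-1*01		GLCTLVAML	EBV
CASSLAPGATNEKLFF	TRBV7-9*01		RAKFKQLL	EBV
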