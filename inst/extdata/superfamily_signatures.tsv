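name	tsd_lengths	terminus_5p	max_mismatch	tsd_motif
hAT	8		0	
hATm	8,9	TAGGGTG	1	
CMC	2,3	CAC	0	
Tc1/mariner	2		0	TA
IS200/IS605	0		0	
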