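barcode_id	role	pool	sequence
bcF_BLA	fwd	BLA	TATCCAGCCCTCTATTGTACTCCT
bcF_ELP2	fwd	ELP2	ATCTCAGCGCCTATGCCACTTCGA
bcF_ELP4	fwd	ELP4	CTGCGCGGTTAGGAGCAATAAGAT
bcF_MEL1	fwd	MEL1	GTGCGTGGGCGCATGGGAGGCGCT
bcR_low	rev	low	GGCCATATTGTATGGAGGTAATCG
bcR_medium	rev	medium	TAAGGTCGCGGTTGGAGGTCCGCC
bcR_high	rev	high	ACACAACTACTCTTTTAAACGGCT
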