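label	chain_a	resno_a	atom_a	chain_b	resno_b	atom_b	expected
nbd_gap_site1	A	50	CA	B	148	CA	17.2
nbd_gap_site2	B	50	CA	A	148	CA	23.6
tm_leu_gap	P	403	CA	P	754	CA	19.2
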