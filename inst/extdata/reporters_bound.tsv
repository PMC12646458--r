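label	chain_a	resno_a	atom_a	chain_b	resno_b	atom_b	expected
nbd_gap_site1	A	50	CA	B	148	CA	8.1
nbd_gap_site2	B	50	CA	A	148	CA	8.1
tm_leu_gap	P	403	CA	P	754	CA	6.6
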