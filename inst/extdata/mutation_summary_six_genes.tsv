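gene_id	amplicon_bp	base_changes	ga	ct	others	aa_substitutions	missense	nonsense	silent
GmSACPD-C	1800	45	21	20	4	38	27	0	11
GmFAD2-1A	1920	42	13	24	5	26	16	0	10
GmFAD2-1B	3320	62	17	22	23	24	10	1	13
GmFAD3A	2480	45	20	15	10	17	12	0	5
GmFAD3B	2480	44	23	16	5	22	14	3	5
GmFAD3C	2440	36	17	10	9	20	13	1	6
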