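gene_id	plant_id	nt_change	aa_change	p16_0	p18_0	p18_1	p18_2	p18_3
GmSACPD-C	F2146	C322T	R108W	9.6	11.7	18.1	50.7	9.8
GmSACPD-C	F186	G554A	G185E	9.4	5.6	23.1	53.7	6.3
GmSACPD-C	F1202	G730A	G244R	10.5	6.0	20.5	52.0	8.8
GmSACPD-C	F1320	G782A	G261D	10.4	5.3	23.1	54.9	4.4
GmFAD2-1A	F1356	C88T	P30S	11.0	3.7	25.0	51.2	7.4
GmFAD2-1A	F765	G116A	G39D	10.0	3.8	27.0	50.2	7.5
GmFAD2-1A	F258	A502C	K168Q	12.2	5.6	34.5	39.3	4.5
GmFAD2-1A	F101	G673A	E225K	10.6	4.6	29.6	45.9	7.7
GmFAD2-1B	F966	A338C	H113P	10.7	4.1	23.0	54.1	6.6
GmFAD2-1B	F782	G505A	V169I	11.7	4.9	27.8	40.2	5.3
GmFAD2-1B	F720	C784T	P262S	10.7	5.1	26.2	50.2	6.2
GmFAD2-1B	F36	C845T	A282V	10.9	4.9	27.6	46.4	8.5
GmFAD2-1B	F903	G1129A	E377K	12.4	5.0	25.1	45.9	7.7
GmFAD3A	F1178	C511T	P171S	11.2	4.5	19.0	57.7	5.8
GmFAD3A	F180	G830A	G277D	17.2	5.5	20.1	45.0	5.2
GmFAD3A	F1012	C835T	L279F	10.4	3.5	34.2	45.7	4.5
GmFAD3A	F1428	G1078A	D360N	10.1	5.1	21.1	56.1	5.6
GmFAD3B	F475	C461T	P154L	10.0	4.3	26.5	53.3	4.6
GmFAD3B	F560	G741A	W247*	10.4	3.3	18.9	60.5	5.5
GmFAD3B	F728	G845A	G282D	12.2	4.2	25.2	52.3	4.6
GmFAD3B	F461	C916T	H306Y	12.5	4.6	17.4	53.1	4.9
GmFAD3C	F953	G112A	A38T	11.2	3.2	23.2	54.9	5.7
GmFAD3C	F846	G383A	G128E	13.9	5.0	17.0	39.6	4.8
GmFAD3C	F1739	A998C	Q333P	9.4	4.5	37.1	41.8	5.1
WT	F-WT			10.8	3.8	20.0	56.2	7.2
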