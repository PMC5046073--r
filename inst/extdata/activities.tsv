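# Inhibitory activities of 37 tea polyphenols on pancreatic lipase.
# ic50 in micromolar; censored = TRUE means the assay reported "> 30"
# (the printed pIC50 4.5229 for those rows is kept verbatim, with the flag
# as the caveat). set: 30 train / 7 test compounds.
compound_no	name	ic50	censored	pic50	set
1	assamicain A	0.13	FALSE	6.8861	train
2	assamicain B	0.21	FALSE	6.6778	train
3	(-)-epicatechin (EC)	30	TRUE	4.5229	train
4	(-)-epicatechin-3-O-gallate (ECG)	0.34	FALSE	6.4685	train
5	(-)-epigallocatechin (EGC)	30	TRUE	4.5229	train
6	(-)-gallocatechin-3-O-gallate (GCG)	0.57	FALSE	6.2441	test
7	(-)-epigallocatechin-3-O-gallate (EGCG)	0.39	FALSE	6.4089	train
8	(-)-epigallocatechin-3,5-di-O-gallate	0.11	FALSE	6.9586	train
9	(-)-epicatechin 3-O-(3'-O-methyl)-gallat	0.74	FALSE	6.1308	train
10	(-)-epigallocatechin-3-O-p-coumaroate	0.97	FALSE	6.0132	train
11	(-)-epicatechin(4b-8)-(-)-epigallocatechin 3-O-gallate	0.16	FALSE	6.7959	test
12	(-)-epigallocatechin (4b-8)-(-)-epicatechin-3-O-gallate	1.23	FALSE	5.9101	train
13	(-)-epicatechin-3-O-gallate-(4b-8)-(-)-epigallocatechin3-O-gallate	0.93	FALSE	6.0315	train
14	(-)-epigallocatechin-3-O-gallate-(4b-8)-(-)-epicatechin 3-O-gallate	0.69	FALSE	6.1612	test
15	(-)-epiafzelechin 3-O-gallate	2.81	FALSE	5.5513	test
16	(+)-catechin (4a-8) (-)-epigallocatechin	8.7	FALSE	5.0605	train
17	(+)-catechin (4a-8) (-)-epigallocatechin 3-O-gallate	0.19	FALSE	6.7212	train
18	(+)-gallocatechin (4a-8) (-)-epicatechin	3.28	FALSE	5.4841	train
19	Oolongtheanin	0.25	FALSE	6.6021	train
20	oolonghomobisflavan A	0.11	FALSE	6.9586	train
21	mono-desgalloyl oolonghomobisflavan A	0.3	FALSE	6.5229	test
22	di-desgalloyl oolonghomobisflavan B	2.29	FALSE	5.6402	train
23	procyanidin B2	8.75	FALSE	5.0580	train
24	procyanidin B3	3.28	FALSE	5.4841	train
25	procyanidin B4	17.29	FALSE	4.7622	train
26	prodelphinidin A2-3'-O-gallate	0.18	FALSE	6.7447	train
27	prodelphinidin B2	3.24	FALSE	5.4895	train
28	prodelphinidin B2- 3'-O-gallate	2.16	FALSE	5.6655	train
29	prodelphinidin B2-3,3'-di-O-gallate	0.1	FALSE	7.0000	train
30	prodelphinidin B4	6.85	FALSE	5.1643	train
31	prodelphinidin B4-3-O-gallate	0.25	FALSE	6.6021	test
32	prodelphinidin B5-3,3'-di-O-gallate	0.61	FALSE	6.2147	train
33	theaflavin-3'-O-gallate	0.13	FALSE	6.8861	train
34	theaflavin-3,3'-di-O-gallate	0.1	FALSE	7.0000	train
35	theasinensin A	0.15	FALSE	6.8239	train
36	theasinensin B	0.3	FALSE	6.5229	train
37	theasinensin C	16.38	FALSE	4.7857	test
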