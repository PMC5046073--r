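# Curated structure registry for the 37-compound activity table.
# Coverage: monomeric flavan-3-ols and their simple esters are encoded with
# full confidence; two dimers (procyanidin B2, theasinensin A) carry
# caveats noted in provenance; polymeric/uncommon compounds whose
# stereochemistry could not be confidently encoded are left without a
# SMILES (structure unavailable) rather than guessed. Neutral (un-ionized)
# hydroxyls are assumed throughout. Formulas verified with Open Babel.
compound_no	smiles	formula	provenance
1			structure unavailable: assamicain-type dimer; stereochemistry not confidently encodable
2			structure unavailable: assamicain-type dimer; stereochemistry not confidently encodable
3	C1[C@@H]([C@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C=C3)O)O)O	C15H14O6	(2R,3R)-epicatechin; literature stereochemistry
4	C1[C@@H]([C@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C=C3)O)O)OC(=O)C4=CC(=C(C(=C4)O)O)O	C22H18O10	(2R,3R)-epicatechin 3-O-gallate; literature stereochemistry
5	C1[C@@H]([C@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C(=C3)O)O)O)O	C15H14O7	(2R,3R)-epigallocatechin; literature stereochemistry
6	C1[C@@H]([C@@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C(=C3)O)O)O)OC(=O)C4=CC(=C(C(=C4)O)O)O	C22H18O11	gallocatechin 3-O-gallate, 2,3-trans relative configuration encoded
7	C1[C@@H]([C@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C(=C3)O)O)O)OC(=O)C4=CC(=C(C(=C4)O)O)O	C22H18O11	(2R,3R)-epigallocatechin 3-O-gallate (EGCG); literature stereochemistry
8	C1[C@@H]([C@H](OC2=CC(=CC(=C21)OC(=O)C5=CC(=C(C(=C5)O)O)O)O)C3=CC(=C(C(=C3)O)O)O)OC(=O)C4=CC(=C(C(=C4)O)O)O	C29H22O15	epigallocatechin 3,5-di-O-gallate; 5-O-galloyl on ring A
9	C1[C@@H]([C@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C=C3)O)O)OC(=O)C4=CC(=C(C(=C4)OC)O)O	C23H20O10	epicatechin 3-O-(3-O-methyl)gallate
10	C1[C@@H]([C@H](OC2=CC(=CC(=C21)O)O)C3=CC(=C(C(=C3)O)O)O)OC(=O)/C=C/C4=CC=C(C=C4)O	C24H20O9	epigallocatechin 3-O-(E)-p-coumaroate
11			structure unavailable: 4b-8 linked dimer; linkage stereochemistry not confidently encodable
12			structure unavailable: 4b-8 linked dimer; linkage stereochemistry not confidently encodable
13			structure unavailable: 4b-8 linked digallate dimer; linkage stereochemistry not confidently encodable
14			structure unavailable: 4b-8 linked digallate dimer; linkage stereochemistry not confidently encodable
15	C1[C@@H]([C@H](OC2=CC(=CC(=C21)O)O)C3=CC=C(C=C3)O)OC(=O)C4=CC(=C(C(=C4)O)O)O	C22H18O9	epiafzelechin 3-O-gallate
16			structure unavailable: 4a-8 linked dimer; linkage stereochemistry not confidently encodable
17			structure unavailable: 4a-8 linked dimer; linkage stereochemistry not confidently encodable
18			structure unavailable: 4a-8 linked dimer; linkage stereochemistry not confidently encodable
19			structure unavailable: oolongtheanin skeleton not confidently encodable
20			structure unavailable: bisflavan skeleton not confidently encodable
21			structure unavailable: bisflavan skeleton not confidently encodable
22			structure unavailable: bisflavan skeleton not confidently encodable
23	[C@@H]1([C@H](O)[C@H](Oc2cc(O)cc(O)c21)c2ccc(O)c(O)c2)c1c(O)cc(O)c2c1O[C@@H](c1ccc(O)c(O)c1)[C@H](O)C2	C30H26O12	procyanidin B2, epicatechin-(4b-8)-epicatechin; constitution certain, stereodescriptors approximate (2,3-cis both units)
24			structure unavailable: catechin-(4a-8)-catechin; linkage stereochemistry not confidently encodable
25			structure unavailable: procyanidin B4; linkage stereochemistry not confidently encodable
26			structure unavailable: A-type prodelphinidin; doubly linked skeleton not confidently encodable
27			structure unavailable: prodelphinidin dimer; linkage stereochemistry not confidently encodable
28			structure unavailable: prodelphinidin gallate dimer; linkage stereochemistry not confidently encodable
29			structure unavailable: prodelphinidin digallate dimer; linkage stereochemistry not confidently encodable
30			structure unavailable: prodelphinidin dimer; linkage stereochemistry not confidently encodable
31			structure unavailable: prodelphinidin gallate dimer; linkage stereochemistry not confidently encodable
32			structure unavailable: prodelphinidin digallate dimer; linkage stereochemistry not confidently encodable
33			structure unavailable: theaflavin benzotropolone skeleton not confidently encodable
34			structure unavailable: theaflavin benzotropolone skeleton not confidently encodable
35	[C@@H]1(c2cc(O)c(O)c(O)c2-c2cc(O)c(O)c(O)c2[C@@H]2Oc3cc(O)cc(O)c3C[C@H]2OC(=O)c2cc(O)c(O)c(O)c2)Oc2cc(O)cc(O)c2C[C@H]1OC(=O)c1cc(O)c(O)c(O)c1	C44H34O22	theasinensin A, EGCG dimer with biphenyl B-B coupling; axial chirality not encoded
36			structure unavailable: theasinensin B; skeleton not confidently encodable
37			structure unavailable: theasinensin C; skeleton not confidently encodable
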