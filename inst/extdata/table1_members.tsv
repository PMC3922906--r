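abbrev	species	rank	AMT1	AMT2	NRT1/PTR	NRT2
Ac	Aquilegia coerulea	eudicot	1	4	48	2
Al	Arabidopsis lyrata	eudicot	6	1	49	6
At	Arabidopsis thaliana	eudicot	5	1	51	6
Cp	Carica papaya	eudicot	2	1	41	2
Cs	Cucumis sativus	eudicot	4	2	49	1
Gm	Glycine max	eudicot	5	5	96	3
Me	Manihot esculenta	eudicot	5	4	61	3
Mt	Medicago truncatula	eudicot	4	3	52	1
Mg	Mimulus guttatus	eudicot	6	2	52	7
Pt	Populus trichocarpa	eudicot	6	5	70	6
Prp	Prunus persica	eudicot	3	4	49	2
Rc	Ricinus communis	eudicot	4	3	41	4
Vv	Vitis vinifera	eudicot	1	1	44	0
Bd	Brachypodium distachyon	monocot	2	6	67	5
Os	Oryza sativa	monocot	2	6	65	3
Si	Setaria italica	monocot	2	6	74	7
Sb	Sorghum bicolor	monocot	2	6	67	4
Zm	Zea mays	monocot	3	5	51	3
Sm	Selaginella moellendorffii	lycophyte	1	0	31	2
Pp	Physcomitrella patens	bryophyte	5	10	18	8
Cr	Chlamydomonas reinhardtii	green_algae	3	0	0	3
Vc	Volvox carteri	green_algae	6	0	1	3
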