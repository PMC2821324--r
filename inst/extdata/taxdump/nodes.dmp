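1	|	1	|	no rank	|
2	|	1	|	superkingdom	|
1224	|	2	|	phylum	|
1236	|	1224	|	class	|
91347	|	1236	|	order	|
543	|	91347	|	family	|
561	|	543	|	genus	|
562	|	561	|	species	|
590	|	543	|	genus	|
28901	|	590	|	species	|
1903411	|	91347	|	family	|
629	|	1903411	|	genus	|
632	|	629	|	species	|
72274	|	1236	|	order	|
135621	|	72274	|	family	|
286	|	135621	|	genus	|
287	|	286	|	species	|
28211	|	1224	|	class	|
356	|	28211	|	order	|
82115	|	356	|	family	|
357	|	82115	|	genus	|
358	|	357	|	species	|
1239	|	2	|	phylum	|
91061	|	1239	|	class	|
1385	|	91061	|	order	|
186817	|	1385	|	family	|
1386	|	186817	|	genus	|
1423	|	1386	|	species	|
186826	|	91061	|	order	|
1300	|	186826	|	family	|
1301	|	1300	|	genus	|
1313	|	1301	|	species	|
1117	|	2	|	phylum	|
1118	|	1117	|	order	|
1142	|	1118	|	genus	|
1148	|	1142	|	species	|
2157	|	1	|	superkingdom	|
28890	|	2157	|	phylum	|
183939	|	28890	|	class	|
2182	|	183939	|	order	|
2183	|	2182	|	family	|
196118	|	2183	|	genus	|
2190	|	196118	|	species	|
2759	|	1	|	superkingdom	|
7711	|	2759	|	phylum	|
40674	|	7711	|	class	|
9443	|	40674	|	order	|
9604	|	9443	|	family	|
9605	|	9604	|	genus	|
9606	|	9605	|	species	|
9989	|	40674	|	order	|
10066	|	9989	|	family	|
10088	|	10066	|	genus	|
10090	|	10088	|	species	|
186623	|	7711	|	class	|
7952	|	186623	|	order	|
7954	|	7952	|	genus	|
7955	|	7954	|	species	|
6656	|	2759	|	phylum	|
50557	|	6656	|	class	|
7147	|	50557	|	order	|
7214	|	7147	|	family	|
7215	|	7214	|	genus	|
7227	|	7215	|	species	|
6231	|	2759	|	phylum	|
119089	|	6231	|	class	|
6236	|	119089	|	order	|
6243	|	6236	|	family	|
6237	|	6243	|	genus	|
6239	|	6237	|	species	|
35493	|	2759	|	phylum	|
3398	|	35493	|	class	|
3699	|	3398	|	order	|
3700	|	3699	|	family	|
3701	|	3700	|	genus	|
3702	|	3701	|	species	|
38820	|	3398	|	order	|
4479	|	38820	|	family	|
4527	|	4479	|	genus	|
4530	|	4527	|	species	|
4890	|	2759	|	phylum	|
4891	|	4890	|	class	|
4892	|	4891	|	order	|
4893	|	4892	|	family	|
4930	|	4893	|	genus	|
4932	|	4930	|	species	|
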