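1	|	root	|		|	scientific name	|
2	|	Bacteria	|		|	scientific name	|
1224	|	Proteobacteria	|		|	scientific name	|
1236	|	Gammaproteobacteria	|		|	scientific name	|
91347	|	Enterobacterales	|		|	scientific name	|
543	|	Enterobacteriaceae	|		|	scientific name	|
561	|	Escherichia	|		|	scientific name	|
562	|	Escherichia coli	|		|	scientific name	|
590	|	Salmonella	|		|	scientific name	|
28901	|	Salmonella enterica	|		|	scientific name	|
1903411	|	Yersiniaceae	|		|	scientific name	|
629	|	Yersinia	|		|	scientific name	|
632	|	Yersinia pestis	|		|	scientific name	|
72274	|	Pseudomonadales	|		|	scientific name	|
135621	|	Pseudomonadaceae	|		|	scientific name	|
286	|	Pseudomonas	|		|	scientific name	|
287	|	Pseudomonas aeruginosa	|		|	scientific name	|
28211	|	Alphaproteobacteria	|		|	scientific name	|
356	|	Rhizobiales	|		|	scientific name	|
82115	|	Rhizobiaceae	|		|	scientific name	|
357	|	Agrobacterium	|		|	scientific name	|
358	|	Agrobacterium tumefaciens	|		|	scientific name	|
1239	|	Firmicutes	|		|	scientific name	|
91061	|	Bacilli	|		|	scientific name	|
1385	|	Bacillales	|		|	scientific name	|
186817	|	Bacillaceae	|		|	scientific name	|
1386	|	Bacillus	|		|	scientific name	|
1423	|	Bacillus subtilis	|		|	scientific name	|
186826	|	Lactobacillales	|		|	scientific name	|
1300	|	Streptococcaceae	|		|	scientific name	|
1301	|	Streptococcus	|		|	scientific name	|
1313	|	Streptococcus pneumoniae	|		|	scientific name	|
1117	|	Cyanobacteria	|		|	scientific name	|
1118	|	Chroococcales	|		|	scientific name	|
1142	|	Synechocystis	|		|	scientific name	|
1148	|	Synechocystis sp. PCC 6803	|		|	scientific name	|
2157	|	Archaea	|		|	scientific name	|
28890	|	Euryarchaeota	|		|	scientific name	|
183939	|	Methanococci	|		|	scientific name	|
2182	|	Methanococcales	|		|	scientific name	|
2183	|	Methanococcaceae	|		|	scientific name	|
196118	|	Methanocaldococcus	|		|	scientific name	|
2190	|	Methanocaldococcus jannaschii	|		|	scientific name	|
2759	|	Eukaryota	|		|	scientific name	|
7711	|	Chordata	|		|	scientific name	|
40674	|	Mammalia	|		|	scientific name	|
9443	|	Primates	|		|	scientific name	|
9604	|	Hominidae	|		|	scientific name	|
9605	|	Homo	|		|	scientific name	|
9606	|	Homo sapiens	|		|	scientific name	|
9989	|	Rodentia	|		|	scientific name	|
10066	|	Muridae	|		|	scientific name	|
10088	|	Mus	|		|	scientific name	|
10090	|	Mus musculus	|		|	scientific name	|
186623	|	Actinopteri	|		|	scientific name	|
7952	|	Cypriniformes	|		|	scientific name	|
7954	|	Danio	|		|	scientific name	|
7955	|	Danio rerio	|		|	scientific name	|
6656	|	Arthropoda	|		|	scientific name	|
50557	|	Insecta	|		|	scientific name	|
7147	|	Diptera	|		|	scientific name	|
7214	|	Drosophilidae	|		|	scientific name	|
7215	|	Drosophila	|		|	scientific name	|
7227	|	Drosophila melanogaster	|		|	scientific name	|
6231	|	Nematoda	|		|	scientific name	|
119089	|	Chromadorea	|		|	scientific name	|
6236	|	Rhabditida	|		|	scientific name	|
6243	|	Rhabditidae	|		|	scientific name	|
6237	|	Caenorhabditis	|		|	scientific name	|
6239	|	Caenorhabditis elegans	|		|	scientific name	|
35493	|	Streptophyta	|		|	scientific name	|
3398	|	Magnoliopsida	|		|	scientific name	|
3699	|	Brassicales	|		|	scientific name	|
3700	|	Brassicaceae	|		|	scientific name	|
3701	|	Arabidopsis	|		|	scientific name	|
3702	|	Arabidopsis thaliana	|		|	scientific name	|
38820	|	Poales	|		|	scientific name	|
4479	|	Poaceae	|		|	scientific name	|
4527	|	Oryza	|		|	scientific name	|
4530	|	Oryza sativa	|		|	scientific name	|
4890	|	Ascomycota	|		|	scientific name	|
4891	|	Saccharomycetes	|		|	scientific name	|
4892	|	Saccharomycetales	|		|	scientific name	|
4893	|	Saccharomycetaceae	|		|	scientific name	|
4930	|	Saccharomyces	|		|	scientific name	|
4932	|	Saccharomyces cerevisiae	|		|	scientific name	|
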