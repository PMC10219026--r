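# BLAST-based phylostratigraphic age index (PAI) scale: rank of the most
# recent common ancestor in which a gene's sequence is detectable.
rank	name
0	Cellular organisms
1	Eukaryota
2	Opisthokonta
3	Metazoa
4	Eumetazoa
5	Bilateria
6	Deuterostomia
7	Chordata
8	Craniata
9	Vertebrata
10	Gnathostomata
11	Teleostomi
12	Euteleostomi
13	Sarcopterygii
14	Dipnotetrapodomorpha
15	Tetrapoda
16	Amniota
17	Mammalia
18	Theria
19	Eutheria
20	Euarchontoglires
21	Primates
22	Haplorrhini
23	Simiiformes
24	Catarrhini
25	Hominoidea
26	Hominidae
27	Homininae
28	Homo
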