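class	Crassostrea gigas	Drosophila melanogaster	Strongylocentrotus purpuratus	Branchiostoma floridae	Homo sapiens
Number of genes	136	104	97	133	255
ANTP	53	47	38	60	100
PRD	30	28	32	29	66
LIM	8	6	6	7	12
POU	4	5	4	7	16
HNF	0	0	2	4	3
SINE	3	3	3	3	6
TALE	23	8	6	9	20
CUT	6	3	1	4	7
PROS	1	1	1	1	2
ZF	4	2	3	5	14
CERS	1	1	1	1	5
Other	4	0	0	3	4
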