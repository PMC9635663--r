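rank	n_genes	consensus_function	consensus_proportion
1	775	Minor tail protein	91.4
2	682	HNH endonuclease	78.1
3	620	Portal	96.0
4	604	Lysin B	95.2
5	541	Ribonucleotide reductase	94.8
6	541	Recombination endonuclease	89.5
7	503	Lysozyme	93.4
8	485	Terminase, large subunit	95.1
9	479	DNA polymerase I	95.2
10	435	Ribonucleotide reductase	95.9
11	416	UvsW-like helicase	92.8
12	413	Terminase, large subunit	95.9
13	409	DNA helicase	78.7
14	401	DNA primase/helicase	88.5
15	396	Terminase, large subunit	95.0
16	394	dNMP kinase	78.9
17	391	Tail tube protein	88.7
18	387	DnaB-like dsDNA helicase	92.8
19	384	Major capsid protein	93.8
20	381	Clamp loader	88.7
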