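rank	n_genes	consensus_function	consensus_proportion
1	946	Minor tail protein	92.3
2	932	Lysin B	95.9
3	689	DNA polymerase I	95.6
4	687	Portal	96.7
5	653	Terminase, large subunit	96.5
6	550	Major capsid protein	96.9
7	548	DNA helicase	93.8
8	540	DNA primase	94.1
9	499	Endonuclease VII	93.0
10	499	Terminase, large subunit	97.2
11	498	Hypothetical protein	63.5
12	494	Hypothetical protein	63.3
13	493	Minor tail protein	91.9
14	474	Tail assembly chaperone	96.4
15	463	Minor tail protein	62.0
16	452	Immunity repressor	87.6
17	446	Head-to-tail connector	58.5
18	445	Head-to-tail connector	54.8
19	445	Hypothetical protein	97.8
20	445	Scaffolding protein	94.6
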