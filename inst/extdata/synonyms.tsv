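pattern	canonical
terl|large terminase|terminase,? large subunit|terminase large-subunit	terminase, large subunit
ters|small terminase|terminase,? small subunit	terminase, small subunit
head-? ?to-? ?tail connector( protein)?|portal connector|adaptor protein	head-to-tail connector
portal( protein)?	portal
mcp|major capsid( protein)?|coat protein	major capsid protein
minor tail protein|mtp	minor tail protein
tail assembly chaperone( protein)?	tail assembly chaperone
lysin ?b|lysb	lysin b
lysin ?a|lysa|endolysin|lysozyme	lysin a
scaffold(ing)? protein|capsid maturation protease and scaffold	scaffolding protein
immunity repressor|repressor( protein)?	immunity repressor
dna pol(ymerase)? ?i?|dna polymerase 1	dna polymerase i
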