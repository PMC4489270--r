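protein_id	gene_name	description
pA	GENA	toy enzyme A of the synthetic pathway
pB	GENB	toy enzyme B of the synthetic pathway
pC	GENC	uncharacterized toy protein C
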