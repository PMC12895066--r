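taxon_id	name	rank	parent_id
2	Bacteria	superkingdom	1
1224	Synthoproteobacteria	phylum	2
101	SynthogenusA	genus	1224
102	SynthogenusB	genus	1224
103	SynthogenusC	genus	1224
2001	SynthogenusA species1	species	101
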