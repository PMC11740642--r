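group	gene_class	n_genes	n_published
contingency	1	18	11
contingency	2	49	2
contingency	3	50	10
additional	2	4	0
additional	3	5	0
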