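metric	count
annotated_genes	39027
genes_ge1	24052
genes_gt1	19008
genes_ge4	12746
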