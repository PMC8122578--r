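partition_label	n_scaffolds	total_bp	scaffold_n50	n_contigs	contig_n50
chromosome_length	8	390045474	51860634	209	6045855
small	236	5840890	24736	248	24000
tiny	557	3462591	9246	558	9246
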