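chrom	fst_count
chr1	27902
chr2	24559
chr3	27679
chr4	26975
chr5	25313
chr6	16433
chr7	25451
chr8	27115
unanchored	1361
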