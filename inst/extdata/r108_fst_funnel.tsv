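stage	count
total_fsts	392396
high_confidence	221275
mapped	202788
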