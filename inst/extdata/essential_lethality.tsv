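lethality_mode	n_genes
partially	250
totally	635
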