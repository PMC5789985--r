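category	n_genes
viable	1784
subviable	258
lethal	649
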