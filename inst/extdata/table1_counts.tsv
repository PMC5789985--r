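mutation_class	all_mutations	isolated	min3_g3	essential
probably_benign	26004	2406	2311	477
possibly_damaging	14412	1314	1270	281
probably_damaging	32669	3077	2982	690
null_class_I	5170	462	441	78
null_class_II	2618	273	268	60
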