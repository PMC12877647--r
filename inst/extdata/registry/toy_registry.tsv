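position	wt	mut	acmg_class
531	R	W	5
562	H	N	5
562	H	P	5
568	W	C	5
611	Y	H	5
626	G	R	4
628	G	R	4
752	R	W	5
823	R	W	5
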