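contig	pos	ref	alt	af
1	1000	A	G	0.35
1	2000	C	T	0.50
2	3000	G	A	0.60
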