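colour	r	g	b
black	0	0	0
grey	128	128	128
white	255	255	255
red	255	0	0
orange	255	150	0
yellow	255	255	0
green	0	200	0
blue	0	0	255
purple	150	0	180
pink	255	170	200
brown	140	75	20
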