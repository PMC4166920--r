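gene_id	cluster	position	family
hoxa13x	hoxax	1	a13
hoxa11x	hoxax	2	a11
hoxa10x	hoxax	3	a10
hoxa9x	hoxax	4	a9
hoxa2x	hoxax	5	a2
hoxb8x	hoxbx	1	b8
hoxb6x	hoxbx	2	b6
hoxb5x	hoxbx	3	b5
hoxb3x	hoxbx	4	b3
hoxb8y	hoxby	1	b8
hoxb6y	hoxby	2	b6
hoxb5y	hoxby	3	b5
hoxb3y	hoxby	4	b3
hoxb1y	hoxby	5	b1
hoxc13x	hoxcx	1	c13
hoxc12x	hoxcx	2	c12
hoxc11x	hoxcx	3	c11
hoxc10x	hoxcx	4	c10
hoxc9x	hoxcx	5	c9
hoxc8x	hoxcx	6	c8
hoxc6x	hoxcx	7	c6
hoxc5x	hoxcx	8	c5
hoxc4x	hoxcx	9	c4
hoxd11x	hoxdx	1	d11
hoxd9x	hoxdx	2	d9
hoxd4x	hoxdx	3	d4
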