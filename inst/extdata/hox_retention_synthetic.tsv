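species	family	copies	clupeocephalan
zebrafish	a13	ab	TRUE
medaka	a13	a	TRUE
zebrafish	a11	ab	TRUE
medaka	a11	a	TRUE
zebrafish	a10	ab	TRUE
medaka	a10	a	TRUE
zebrafish	a9	ab	TRUE
medaka	a9	a	TRUE
zebrafish	a2	ab	TRUE
medaka	a2	a	TRUE
zebrafish	b8	ab	TRUE
medaka	b8	a	TRUE
zebrafish	b6	ab	TRUE
medaka	b6	a	TRUE
zebrafish	b5	ab	TRUE
medaka	b5	a	TRUE
zebrafish	b3	ab	TRUE
medaka	b3	a	TRUE
zebrafish	b1	ab	TRUE
medaka	b1	a	TRUE
zebrafish	c13	ab	TRUE
medaka	c13	a	TRUE
zebrafish	c12	ab	TRUE
medaka	c12	a	TRUE
zebrafish	c11	ab	TRUE
medaka	c11	a	TRUE
zebrafish	c10	ab	TRUE
medaka	c10	a	TRUE
zebrafish	c9	ab	TRUE
medaka	c9	a	TRUE
zebrafish	c8	ab	TRUE
medaka	c8	a	TRUE
zebrafish	c6	ab	TRUE
medaka	c6	a	TRUE
zebrafish	c5	ab	TRUE
medaka	c5	a	TRUE
zebrafish	c4	ab	TRUE
medaka	c4	a	TRUE
zebrafish	d11	ab	TRUE
medaka	d11	a	TRUE
zebrafish	d9	ab	TRUE
medaka	d9	a	TRUE
zebrafish	d4	ab	TRUE
medaka	d4	a	TRUE
zebrafish	a1	a	TRUE
medaka	a1	a	TRUE
coelacanth	a1	ab	FALSE
zebrafish	a5	a	TRUE
medaka	a5	a	TRUE
coelacanth	a5	ab	FALSE
zebrafish	b13	a	TRUE
medaka	b13	a	TRUE
coelacanth	b13	ab	FALSE
zebrafish	d3	a	TRUE
medaka	d3	a	TRUE
coelacanth	d3	ab	FALSE
zebrafish	d12	a	TRUE
medaka	d12	a	TRUE
coelacanth	d12	ab	FALSE
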