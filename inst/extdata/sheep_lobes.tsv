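id	volume_pct	height_pct	side	lobe
19	12.1	72	left	apical
20	31.1	18	right	diaphragmatic
21	4.9	30	right	accessory
22	9.4	45	right	middle
23	13.5	75	right	apical
24	29.1	20	left	diaphragmatic
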