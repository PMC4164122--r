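segment_id	side
19	right
20	right
21	right
22	right
23	right
24	right
25	right
26	right
27	left
28	left
29	right
30	left
31	left
32	left
33	left
34	right
35	left
36	left
37	left
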