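leaf_id	segment_id
7	19
7	20
7	21
9	22
9	24
10	23
10	29
12	25
12	26
13	34
14	33
14	35
16	32
16	36
16	37
17	27
17	28
18	30
18	31
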