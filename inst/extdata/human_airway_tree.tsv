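parent_id	child_id
1	2
1	3
2	4
2	5
4	7
4	9
5	8
5	10
8	12
8	13
3	6
3	11
6	14
6	15
11	16
11	17
15	18
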