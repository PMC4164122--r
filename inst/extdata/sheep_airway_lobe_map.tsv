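leaf_id	segment_id
3	19
3	24
4	20
4	21
5	23
6	22
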