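group	members
G1	1,2,3,4,5,6,7,8,9
G2	8-1,8-2,8-3
G3	8-3_1,8-3_2
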