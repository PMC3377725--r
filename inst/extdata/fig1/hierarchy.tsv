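composite	children
8-3	8-3_1,8-3_2
8	8-1,8-2,8-3
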