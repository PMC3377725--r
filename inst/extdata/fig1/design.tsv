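array_id	tail_unit	head_unit
A01	1	2
A02	2	3
A03	3	4
A04	4	5
A05	5	6
A06	6	7
A07	7	8-1
A08	8-1	8-2
A09	8-2	8-3_1
A10	8-3_1	8-3_2
A11	8-3_2	9
A12	9	1
A13	1	3
A14	2	4
A15	3	5
A16	4	6
A17	5	7
A18	6	8-1
A19	7	8-2
A20	8-1	8-3_1
A21	8-2	8-3_2
A22	8-3_1	9
A23	8-3_2	1
A24	9	2
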