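unit_id	individual	section	tech_rep
1	1		
2	2		
3	3		
4	4		
5	5		
6	6		
7	7		
8-1	8	8-1	
8-2	8	8-2	
8-3_1	8	8-3	8-3_1
8-3_2	8	8-3	8-3_2
9	9		
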