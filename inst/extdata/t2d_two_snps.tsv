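snp_id	r0_1	r1_1	r2_1	s0_1	s1_1	s2_1	r0_2	r1_2	r2_2	s0_2	s1_2	s2_2
rs1005316	13	224	457	44	211	399	89	669	1708	89	913	1856
rs2876711	99	322	272	121	351	182	389	1191	989	484	1404	987
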