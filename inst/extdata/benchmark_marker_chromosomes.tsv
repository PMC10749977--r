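chromosome	cd_n	fi2_n	major_n
1	4722	69	16
2	3565	36	10
3	3249	28	9
4	3552	42	5
5	1384	15	4
6	2508	23	2
7	3796	37	8
8	2127	18	8
9	2426	22	5
Scaffolds	777	5	2
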