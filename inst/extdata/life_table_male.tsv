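age	alive	lx_printed	d_printed	q_printed	ex_printed
0-3	228	1.0000	112	0.4912	1.8805
3-6	116	0.5088	65	0.5604	2.0168
6-9	51	0.2237	16	0.3137	2.2694
9-12	35	0.1535	13	0.3714	2.0672
12-15	22	0.0483	11	0.5000	2.0043
15-18	11	0.0219	6	0.5455	2.4028
18-21	5	0.0132	2	0.4000	1.7019
21-24	3	0.0088	1	0.3333	1.5016
24-27	2	0.0044	1	0.5000	1.0029
27-30	1				0.5000
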