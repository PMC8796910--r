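age	n_x	B_x	mean_litter	total_printed	daughters_printed	mx_printed
0-3	353	0	0	0	0	0
3-6	171	0	0	0	0	0
6-9	73	0	0	0	0	0
9-12	55	41	4.83	198.03	99.02	1.800
12-15	36	33	5.27	173.91	86.96	2.415
15-18	18	17	5.16	87.72	43.86	2.437
18-21	8	0	0	0	0	0
21-24	6	6	5.29	31.74	15.87	2.645
24-27	5	4	5.08	20.32	10.16	2.032
27-30	2	1	5.00	5.00	2.50	1.250
30-33	1	0	0	0	0	0
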