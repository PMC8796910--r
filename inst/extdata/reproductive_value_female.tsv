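age	pivotal_age	n_x	lx	mx	lxmx	x_lxmx	Vx_printed
0-3	1.5	353	1000	0	0	0	1.398
3-6	4.5	171	487.18	0	0	0	2.872
6-9	7.5	73	347.62	0	0	0	4.023
9-12	12	55	261.90	1.800	471.42	5657.04	5.341
12-15	14	36	171.43	2.415	414.00	5796.05	5.369
15-18	16	18	85.71	2.437	208.88	3342.00	6.064
18-21	20	8	68.97	0	0	0	4.411
21-24	24	6	63.83	2.645	168.83	4051.93	4.766
24-27	26	5	53.19	2.032	108.08	2810.13	2.545
27-30	29	2	21.28	1.250	27.288	791.34	1.282
30-33	31.5	1	17.70	0	0	0	0
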