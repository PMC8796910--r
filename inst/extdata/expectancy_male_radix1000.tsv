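age	lx	dx	qx	Lx	Tx	ex
0-3	1000.00	467.89	0.468	798.72	1875.45	1.88
3-6	532.11	237.31	0.446	408.96	1076.73	2.73
6-9	294.86	92.49	0.370	248.56	667.77	2.27
9-12	202.31	75.14	0.371	164.74	419.21	2.07
12-15	127.17	61.30	0.482	96.52	254.47	2.00
15-18	65.87	9.05	0.137	61.35	157.95	2.40
18-21	56.82	22.73	0.400	45.46	96.60	1.70
21-24	34.09	11.36	0.333	28.41	51.14	1.50
24-27	22.73	11.37	0.500	17.05	22.73	1.00
27-30	16.36	16.36	1.000	5.68	5.60	0.50
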