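age	lx	dx	qx	Lx	Tx	ex
0-3	1000.00	512.82	0.513	782.46	2113.69	2.11
3-6	487.18	139.56	0.286	417.40	1331.23	3.17
6-9	347.62	85.72	0.247	304.76	913.83	2.63
9-12	261.90	90.47	0.345	216.67	609.07	2.33
12-15	171.43	85.72	0.500	128.57	392.40	2.29
15-18	85.71	16.74	0.195	77.34	263.83	3.08
18-21	68.97	5.14	0.075	66.40	186.39	2.70
21-24	63.83	10.64	0.167	58.51	120.09	1.88
24-27	53.19	31.91	0.599	37.24	61.58	1.16
27-30	21.28	7.58	0.356	17.49	24.34	1.14
30-33	13.70	13.70	1.000	6.85	6.85	0.50
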