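age	alive	lx_printed	d_printed	q_printed
0-3	353	1.0000	182	0.5156
3-6	171	0.4844	98	0.5731
6-9	73	0.2068	18	0.2466
9-12	55	0.1558	19	0.3455
12-15	36	0.1020	18	0.5000
15-18	18	0.0510	10	0.5556
18-21	8	0.0227	2	0.2500
21-24	6	0.0170	1	0.1667
24-27	5	0.0142	3	0.6000
27-30	2	0.0057	1	0.5000
30-33	1	0.0028		
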