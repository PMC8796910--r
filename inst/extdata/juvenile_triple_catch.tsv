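year	month	sex	B1	R13	B2	R23	Shat_printed
1989	4	male	8	4	53	52	0.5196
1989	5	male	53	35	21	21	0.5943
1989	6	male	21	9	6	5	0.6429
1989	7	male	6	2	14	14	0.3589
1990	4	male	14	6	92	88	0.4532
1990	5	male	60	26	14	11	0.5833
1990	6	male	5	3	10	11	0.6000
1990	7	male	6	3	20	30	0.4482
1991	4	male	20	9	45	42	0.4821
1991	5	male	25	12	18	16	0.5760
1991	6	male	10	5	6	6	0.6060
1989	4	female	13	6	60	57	0.5769
1989	5	female	60	33	13	12	0.6500
1989	6	female	13	5	8	5	0.7692
1989	7	female	8	3	31	29	0.4152
1990	4	female	22	10	110	102	0.4950
1990	5	female	70	34	39	31	0.6314
1990	6	female	22	12	9	8	0.7013
1990	7	female	2	1	39	39	0.5132
1991	4	female	32	17	110	109	0.5361
1991	5	female	87	39	40	29	0.6404
1991	6	female	22	8	30	20	0.6459
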