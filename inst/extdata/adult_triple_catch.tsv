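year	month	sex	B1	R13	B2	R23	Shat_printed
1989	4	male	10	5	85	79	0.5449
1989	5	male	85	42	8	7	0.6588
1989	6	male	8	5	16	14	0.7692
1989	7	male	16	6	21	13	0.6563
1989	8	male	21	6	15	9	0.5357
1989	9	male	15	4	5	4	0.4444
1989	10	male	5	2	14	11	0.5600
1990	4	male	14	7	32	29	0.5714
1990	5	male	32	14	9	7	0.6563
1990	6	male	9	5	5	5	0.6944
1990	7	male	5	3	6	10	0.4000
1990	8	male	10	3	6	6	0.3600
1990	9	male	6	2	3	4	0.3333
1990	10	male	3	1	18	13	0.5000
1991	4	male	18	8	20	17	0.5555
1991	5	male	20	9	8	7	0.6000
1991	6	male	8	4	5	5	0.6250
1991	7	male	5	2	9	7	0.6000
1991	8	male	9	3	7	6	0.4600
1989	4	female	10	7	88	82	0.7080
1989	5	female	88	69	27	27	0.7356
1989	6	female	27	22	35	34	0.8642
1989	7	female	35	15	9	7	0.6429
1989	8	female	9	4	13	11	0.5778
1989	9	female	13	5	7	6	0.5385
1989	10	female	7	3	13	10	0.6190
1990	4	female	13	8	40	37	0.6838
1990	5	female	40	30	17	17	0.7969
1990	6	female	17	12	7	7	0.8235
1990	7	female	7	4	6	6	0.6857
1990	8	female	6	3	7	7	0.5833
1990	9	female	7	3	5	5	0.5357
1990	10	female	5	3	31	30	0.6276
1991	4	female	31	21	23	23	0.7082
1991	5	female	23	16	18	18	0.7366
1991	6	female	18	14	18	18	0.8235
1991	7	female	18	10	7	7	0.6481
1991	8	female	7	2	9	6	0.5143
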