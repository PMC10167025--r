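r	i_t	i	e	v1_1	v1_2	v2_1	v2_2	v3_1	v3_2	v4_1	v4_2	avg_err_c
15	2.029	2	0.029	28	29	31	31	43	46	37	36	0.032
10	3.044	3	0.044	28	29	31	31	43	46	37	36	0.032
6	5.073	5	0.073	29	29	30	31	43	46	37	35	0.035
5	6.088	6	0.088	28	29	31	31	43	47	37	35	0.038
3	10.146	10	0.146	30	26	29	30	44	46	36	35	0.052
14	2.174	2	0.174	30	31	33	34	46	49	40	38	0.049
8	3.805	4	0.195	27	27	30	30	41	42	35	34	0.072
2	15.219	15	0.219	28	29	31	29	44	49	36	33	0.059
11	2.767	3	0.233	25	26	28	28	39	42	34	32	0.116
13	2.341	2	0.341	33	33	36	36	50	53	43	41	0.133
7	4.348	4	0.348	31	31	34	34	46	48	40	39	0.058
9	3.382	3	0.382	31	32	34	34	48	51	41	40	0.083
4	7.61	8	0.39	27	27	30	30	41	42	35	34	0.072
12	2.537	3	0.4635	23	24	26	26	36	38	31	30	0.185
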