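tag_id	trial	err_d
8	1	9.6
8	2	10.5
8	3	8.5
8	4	7.2
8	5	6.9
12	1	17.2
12	2	16.8
12	3	12.6
12	4	12.5
12	5	14
21	1	13.1
21	2	16.6
21	3	17.1
21	4	16.6
21	5	6.6
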