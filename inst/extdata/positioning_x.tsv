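tag_id	trial	err_x
8	1	-9.1
8	2	-10.4
8	3	-8.3
8	4	-5.9
8	5	-5.1
12	1	-16.5
12	2	-14.4
12	3	-10.1
12	4	-11.1
12	5	-11.5
21	1	-8.6
21	2	-15.2
21	3	-16.2
21	4	-11.7
21	5	5.2
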