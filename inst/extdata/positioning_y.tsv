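tag_id	trial	err_y
8	1	-3.2
8	2	-0.8
8	3	-2
8	4	-4.1
8	5	-4.6
12	1	-4.7
12	2	-8.7
12	3	-7.6
12	4	-5.8
12	5	-8
21	1	-9.9
21	2	-6.7
21	3	-5.4
21	4	-11.8
21	5	-4
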