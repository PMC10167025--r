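video	n_gt
v1_1	30
v1_2	30
v2_1	32
v2_2	32
v3_1	44
v3_2	44
v4_1	37
v4_2	37
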