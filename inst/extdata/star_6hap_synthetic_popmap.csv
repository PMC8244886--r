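id,population
H1_1,H1_1
H1_2,H1_2
H1_3,H1_3
H1_4,H1_4
H1_5,H1_5
H1_6,H1_6
H2_1,H2_1
H2_2,H2_2
H2_3,H2_3
H3_1,H3_1
H3_2,H3_2
H3_3,H3_3
H4_1,H4_1
H4_2,H4_2
H4_3,H4_3
H5_1,H5_1
H5_2,H5_2
H5_3,H5_3
H6_1,H6_1
H6_2,H6_2
H6_3,H6_3
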