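>H1_1
AAAAAA
>H1_2
AAAAAA
>H1_3
AAAAAA
>H1_4
AAAAAA
>H1_5
AAAAAA
>H1_6
AAAAAA
>H2_1
CAAAAA
>H2_2
CAAAAA
>H2_3
CAAAAA
>H3_1
ACAAAA
>H3_2
ACAAAA
>H3_3
ACAAAA
>H4_1
AACAAA
>H4_2
AACAAA
>H4_3
AACAAA
>H5_1
AAACAA
>H5_2
AAACAA
>H5_3
AAACAA
>H6_1
AAAACA
>H6_2
AAAACA
>H6_3
AAAACA
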