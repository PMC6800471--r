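>front_primer
AGTTGGTCAAGTAGCGAAATTGAG
>end_primer
AACTGAACTTGGGAATACTGTCTC
>probe
TGATGCAGGAAACCCAGCGAGCTATTGAA
>bc01
GCTACATGACTGCGCA
>bc02
TTGTACCCTGTGTGCT
>bc03
AGCACTCAACCTTCCG
>bc04
CTTTCTGTGAGACGAC
>bc05
AAGAAGCTAACAGACA
>bc06
TTTGTAGGCGTTGAGG
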