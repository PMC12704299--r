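>TRBC1_2 consensus amplicon, exon 1 of TCR beta constant regions 1 and 2
GGTCTCGGCCACCTTCTGGCAGAACCCCCGCAACCACTTCCGCTGTCAAGTCCAGTTCTA
CGGGCTCTCGGAGAATGACGAGTGGACCCAGGATAGGGCCAAACCCGTCACCCAGATCGT
CAGCGCCGAGGCCTGGGGTAGAGCAGGTGAGTGGGGCCTGGGGAGATGCCTGGAGGAGAT
TAGG
>TRAC amplicon, TCR alpha constant region
CTGCTCTGGATGCTGAAAGAATGTCTGTTTTTCCTTTTAGAAAGTTCCTGTGATGTCAAG
CTGGTCGAGAAAAGCTTTGAAACAGGTAAGACAGGGGTCTAGCCTGGGTTTGCACAGGAT
TGCGGAAGTGATGAACCCGCAATAACCCTGCCTGGATGAGGGAGTGGGAAGAAATT
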