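>sA_F
AACGTATAGTTCATCGAGAA
>sA_R
CAATCACAAAGCCGCGAGCC
>sA_P
AGTTTTCCCCATGCTTAATT
>sB_F
CAGTTCGCGAGAGCAGTACG
>sB_R
CTTACACTGGCTTCCACCCT
>sB_P
ACTGTCCGGTGATAACCTGG
>sC_F
CCGGATAGCCTCCCTCTTCA
>sC_R
AAACCTGGTGACCCGCAGCT
>sC_P
CTCCTGCGGCGAGTTATGGC
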