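>synthA_template synthetic
TATCCAGCCCTCTATTGTACTCCTATCTCAGCGCCTATGCCACTTCGACTGCGCGGTTAGGAGCAATAAGATGTGCGTGGGCGCATGGGAGGCGCTGGCCAACGTATAGTTCATCGAGAAATATTGTATGGAGGTAATCGTAAGGTCGCGGTTGGAGGTCCGCCACACAACTACTCTTTTAGTTTTCCCCATGCTTAATTAAACGGCTAGACGAGTACGGACAGACCACTTTGCGTGACTCGCGGAGTCTAGTCGATCTCAGGCACACAAATAAAACTGTGGCTCGCGGCTTTGTGATTGGGCCTCTTCCCGCGGCCTGTATAGGTAGCTTACGCTTCACCAGACCCTTCCCTCTCTGATCCCAGCTAAGATTGCCACAGGACCGAGCACCTATATGGGCACGTCATCAGAGTAATCCAAGACCTGCGGGGACGAGAGGCAGCACATAGAACGTCCGAAGTCGCCATTACGGCGATACGCTTTTTAGGGCATTGTTCGCC
>synthIR_template synthetic inverted-repeat
CAACTGGTGGAACAAGCTGTACATTTGGATTATCGACTCAGCTTGTTACCGATCACTGTAGCCTTCGAAAGGTCCGCCGCACGTGATGGCAAGCCAATCACTACCGACTTTCCATTCCGCCCACAGGAAGGGATAGGTTTAAGCGTGGACCTTACACTGGCTTCCACCCTACCCATAGACGTGGGTCTCAGATGCAAGACAGGTTGGCACGAACCCCCAAGTTCCTCCGCGGATGGAGGAGATGTGACAGAGTGACCTTCGCGTTACTTATATACTAGCCAATACTGTAGTACGACGTTCTGGTGATGGATGCGGTGAAACCTATACGTTCTGTAAAAGGGTGGAAGCCAGTGTAAGTCGAATGCGGAAAGCCACACACGGGCAGTGTCCGCCTCACCAACCAGGCGAGATTCCGTTCTACGTCCCTTAGCGGAGAGCCAACAATAATATACCTAGTGATCCCTAAAGGATTCAAGCGAGCTCAAGAAACATATATCAACGCGATAT
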