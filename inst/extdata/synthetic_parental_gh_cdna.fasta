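>NN_GH_cdna
AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGCAAGCTCAATCTA
CTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTT
GAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTACAGTT
CTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTC
ACGATCTTTATCCCTGGAGATAAGTTGGGAGGAGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGA
GTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGAATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATCCC
TTAAGCCAAGAGCAAATATACGACCAATCTAAGGAACGGCCGTGAACGGATCTCTGACTATCACAACCGTGAATGTCAGA
TGGATCTAGATGGCTCTTGTCTACTGTCTATTATTTTATCAGGGGAGTTGGATCGGGCTGGAGGAAATTGTATCAGGCCG
GGGACTGAGTGCGTACCCTCCTGCGCCTGCTGCGACCGTGACAGCGAGCAGCGTTTTAGGATGCGAGGGGGACCTTATTG
AAGTACGGAGAGTCTGCAAACTTGCACTCAACCCCCCTGATCAGAAGAGCGCGACTCCACACTTACACCTAGCGCCATAC
ACGCGG
>BB_GH_cdna
AACGGACGATGCGTGTATGGCTGTGAGACTAAGCTCTACTCGAAACATCTTTCGTGCCACATAAGTGCAAGCTCAATCCA
CTCATATCGCATCCCCACACCACGAGGACCGTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTT
GAGGGCTTGATAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCCATCTACAGTT
CTCAGCAACGCAGGAGGATCGTCGGTCTTACCTGGTGAAGTAGTAATGATAGGATCTCACACTACATTTTTGCAATCCTC
ACGATCTTTATCCCTGGAGATAAGTTGGGAGGGGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGA
GTGTGTCGATCTGCTTCTACTACTAAGAAGTGCGCCCCCGAATCTACGCTTGGTGGCTACCGCACTCAAGGTGTAATCCC
TTAAGCCAAGAGCAAATATACGACCAATCTAAGGAACGGCCGTGAAGGGATCTCTGACTATCACAACCGTGAATGTCAGA
TGGATCTAGATGGCTCTTGTCTACTGTCTATTATTTTATCAGGGGAGTTGGATCGGGCTGGAGGAAATAGTATCAGGCCG
GGGACTGAGTGCGTACCCTCCTGCGCCTGCTGCGACCGTGACAGCGAGCAGCGTTTTAGGATGCGAGGGGGACCTTATTG
AAGTACGGAGAGTCTGCAAACTTGCACTCAACCCCCCTGATCAGAAGAGCGCGACTCCACACTTACACCTAGCGCCATAC
ACGCGG
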