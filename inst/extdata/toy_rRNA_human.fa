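>rRNA_human_18S_toy
GCCTGCTGCGGAGTTAATGAGCGACACACGATTGAAGTAAACAGTGTATTCCTAATAGCCGAGGATGAGC
GTTGCTTTCAAGAAGCGACAGCCTGTTCAAGGATACTTTTAAAGACGGCCGACCAACGCCTGAGGGACAG
CCACAGCACTTCAATCAGCACAATCTGAGGTCCGTCCACTAGTAAGTAGAGCCCAAGAAAATTACGTTCA
GCAAGGGCCTCTACTTTATATACAACCCCGTCTTTGAAACAACCCGGTAGTGGTTTCGCTAGGTACGTCG
TGGACATAGCTACAGCGAATTACGGGTAGGGCCCTCCCTACCAACTTGGGGGGGGATAGACCGTCATTAC
AGGCACGAGTTAAGCACGTTCAGTCAGCGCCATTAGTAAGCCATGTGAGTCGCCACTGAGCGATGCTGAG
GGCACCCGGCGTGCAACCTTTATTTCGGAGAAAGAGGTCCGAGTTTAATAGAATTGGTCGTACTGCGCAA
TGATTCTAGTCACTTGATCAGCACGAGGGGCCCTGACTACCAGCAGGGACAGCACACTGAGGCATTCGGT
GAATTATGGACGACCGCAGTGATGATCGATGACCTTCACCTAGCTAGACGACCCTTATGCCTTTTACTCG
TGTCCAGATTGCTCGACAATGGTCTTTTAGCTTACTCACTGTCTGCACTGCCACCACTATGCCGAGGGCT
AGCATGATCCTTCGCAACAAACCATTGGAGTGGCGCGTTGTACATTTTCTTGAGTATGGAGTTCCTTTAG
TTGGTACCTGCGGCGAACGAATCCGCTCGTCTGCATAAAGGAAGTCGATATAACTATTAGATCTGTAAGA
ATAGGTGCAGTTCATTTACCTTTGTAGAGTCAGTCGCTTCGGTTTAATTAACATGAAGGCCCAATTGCGG
TAGACACTGTTTACGACGAAACTTGGATCATTCCAGCCAGATCCATTTAGGGCGGGATTTAGTTACCGAG
GTTAATCGAGCAAATCACGACCAAACGCGCAGATGAACAAGGGTTTTGAGACTCAGACGGGCTTGTCGCG
GGATAAAGCGACCGAGGTATAACGGCCCCATTTACGCTCGTGGAGTGATAATTTTCAGAGGTGGCCCCGT
CGAGGTTCGAACGACGCGTTCAGTCGCGCACGATGCTAGTTTTGGGCACCTCCAGTGATTTTACCCCAAG
ACGCCCCACTGTTGCTCGCCAGAGGTAGCATGGCGCTTTTAGGTACCCTATGGTCGAGGTAGTCTCTAGA
GGTGCTCTTCATGTCGTAATTGTTCAATTATGAGGGTAGACCCGCACATTCATGTGGCAGCTCTGGTAAA
CTGCATGCTCAAACGGCTCCCCTCTCCCCGCGAATGCTCGGGCACGCCGTGCGTTCGAGATATTAGTACT

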