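>tRNA_toy1
CTACCGGAGCCGCACGCCTGGTAGCGCCCGAATGGGGCACGCCTGGTCGCCCCTTTCCCCGGGTCAGACG
CTTGGTCTATTTAATAGATACCCAGAAGTCCAATGTCCTTTTGCAGGGATCACGGGCCGACCACTTATGC
TTAAACATATAATAATGTTGCCTCGCTCGGACCGTCCCTTATCAACAGCTCGTCGATTCGACGGAGGATC

>tRNA_toy2
TAACGTTGAGTGCTTATATAGGAACCGCTGCTCTGGTGCGACCATGAAGGCCTTAACCAGTCCGATTTTT
AAGTGCCGACCTGCGGTGCTAGCTGCCATTTTGCAGTCTCGGACATGGGGCTTTCTCAGCACGAGTTAAT
GAACAGGTAACGCTTTGAATAGTGATAGCCAACATCAGGATTCTCATACAAAGCCTTATGGTCGGAAGAC
TGTTACTCAGGGGGTGTTCG
>tRNA_toy3
AGTCAAGGTGCAGACTGTAAACATTTATCCAATTTTTTAATACCCGACAGGGGGGAATCGATCCGATCGG
CTCTGAGATAGGCCTATCAACAATGCGACCCTAAAGGGACGGAGCATCTTAGTTTCGGCCCTGGGGCAAG
TCCTAGACGTATTGAACCAAGCAGTTTAAACATATACTTAGTCTAGGGCGCGTCTTGGACCGTATATGGG
ACCAGCAAAGATTTAGTGCTGAATGTCGCGCTATCAATGA
>tRNA_toy4
GCGGACGGTTACATCACATGGCGCCTGGATTTTCGTCGTCATTCACCATCTCAAGCCGCTTAGTGTAAGT
ACTTTACTCTTGCGGTATGGTAGTACGAGCACTGACGACTGTTTGCTAAACGCTAGAGGGAGCAGTGGCA
ATTTTTGAATACCTTACAGTGCATTGTCCGAATTTTTTCCCTTATTCGTCCTCCTAGCACAATGTAGCCT
AGGTCCACTGTCACATAGCCGTTCCTTCATGACGTGGGATTCGAGTGAAAATCTTGACTT
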