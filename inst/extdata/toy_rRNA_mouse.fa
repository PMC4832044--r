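>rRNA_mouse_18S_toy
CGGTATCTAATTACGAATTAATACTCCAACACGGGCAGGCGTCCCAACGTTACGCCCATTTGACCTCCCT
AAGCCCCTGGTCCCATCGGCCTGGCATCAGTCGACACTCGGTTCTATAAAGGAGGAATATAAGACTCCTA
ATCCAAACGGAAATGCGTCAGAGCGATCGGCGGCAGTACCCTTCTTTTCTATTCGGGTTCACGGGGCGCA
TCCACCTATGATGTGTACGCGCGGATCAGGGCTGGACATTCCTAGAAGGGTAATGAGCAGGTAGTCTAAG
ATTCACTATGAGACGCGACCCCAACTCCAGGTAAACTTGGGAATGTGCTCCGTTGAGATAGGGCTGGAGG
CGTCGTGACATCTAGTCAACTATTAGAAGGCGTCAGCTGAGACGTGGCATGGCCCAGCCATTCAAGGTTC
CAACGCTATACCAGTAACTTCAGGTTGTGGAGCCTTATACTGGGGAATTTCGTTTGGAATATACAGACCG
TGAGGCTACACATCCTCCTTCATTGCTGCTCCCGTGCACGGTCGTGCTTGCAGTTTTTGCTCCAAACGGA
GACCGCAGTAACCGGCTGTGTTGTATGGGCGTAAAAAGCGCTTATTCTTTGTGATAAACAGCCCACCCAA
TTCCTATCGCTACGCAGCATGACTTGTAGAAGCTTTATGTGAGCGAGGTTCTTCCCGTGGCAAGTAACCC
GTAATAGTGAGTTACCACTAAGACTGAAGTTATGGAATTACTTGACAAGAGCCCTACCAGCCTCTGAATA
CACAGAGCGAAATTCAGGGTACCCCCTAGATCTGGCGTCGCTACCGACCGGTACTGGACCCATTCAGGGG
CTCACACGCATTCGCAGCCTTCATTCGGACCTGAGCTAACGTGTATTTTTCACACGCATTGCATTAGAAT
ATGCTGTCCAAATACAGTTGTGGTACGGGCGCAGTATGCGATGCCCCGTATCTATAAACGTGATACCCCT
AGACTTACAGAGTACCCGGTGCGATAGACTGCTCGAGGCTCGATCGCCCCTCCTCCGGGCGGTAGGCAGA
AGAGGCTATGGAAAACGTGCAACTAAGAAAAATCTGTTTGCATCATAGTTTACGCTTCACCTCCGCGATG
AAAATGCCGTATCAATAGGGTGTCGCCAATCCCGGGTCAGATGAGGTGATATTTGTAATCCCTGCGTGGG
CACGCCTAGG
>rRNA_mouse_28S_toy
TGCACATAGTCAACGTGATGACTCACTTACTAAACGCTCAGCTCGATTCCTCAGTGCAGGTATCAGGACA
CCTAGTTCGTAGTTGGGCATCACACTGGACTGAAACGGAGTTGGGCCAACTATAAGTGCTTACCTATTCC
CGCAGGCCTATGCATGCATCGAGGTGACTCGACCTTCGCGCCGAGTCGGTCGTGCTTGTGACTTTTTATC
GCTTAACATTTGCGGGTTTAGTATCAAGGGGGGATGAATAAGCTGAAAACTACTGTAGGCGCCTTGCGAT
ACCAGGCCGCCTTTAACACCCGGGAGACTTGCACATATTACTGTATATCTCTATGGTACCAGCCGCGCTG
TGGCTGTCGCGGAGGGGGTTAAGAACTAGTGGTGGAGCCTAATGGGTTTCGAGTGATTCGTAGCTCGACG
GTTTGCCGTTACTTCCCAAGGCAAAGCATCAGCTAAAGGATCGACGTCAACGCTGCATCTCTATTGCAAC
ATAGCTACTATGGGAAAGAGACGATCTCATTGAGCGTTGAAGCGTACTGACCAAACGTTTACTACCATTA
TACGGGAAAACTCCCGGGGCATGCCCAGTTCGAGTCTCTTCAATCCCATCTCTAATATCCTTGCGGACAT
ACAATTACGGGTAGAGAGCAGGTTTGACGGACTTGCCGAGAGTACAGCACAGTGTCGTATTCTGTGGATG
CACGATTAATAGCATGGTAGCTGATCTCCACCGATGGAATGATATCCTAATCACATCGTCCGTCTATGTA
ATCCTCACGTGAGGACAACTGTATCCGTGTAGCGGACACCCCAATACCATGGAGTACTGCTAGGAGGATT
ATTTACTTGGGAGTCCCGCTCAAGTACTTAGAATATGACGACACTACGGAATAACGATAACTCATTTACG
TACTTTTTGATATTTCTAGAGGTTTGGTGACAACTTGAACGACATTTTCATGGCGCGGACACCAGGCAAC
CGGAATGGCCCATGGAGGTTTCGGGGTTGATCAGCGAGCGCGATTCGTATACTTAATCGTATGAGAACAA
CATCCAAGGGGTTGACTTCATGTAAGAAACGATTATGGTGAGGCGTGTCACATCCGATAACAAGTCCCTG
TCTCGAGACTGAGGCGGGATATGATAAAGGAATCAGCTTTCAGGGCTAATATAGTGCCTAGCGTATTGTC
GTAAGTTGTGACGCGATTCAGAGGGGGACATCTGCAGCTGCAGAACTGTCAAAGGATTTTTAGCCAAGTT
AGGCCGCACACTTCCATATGGTCTCAATAGCATCGGGCATATCAGTTATTCGGGGAAGTTGCTCCATCTA
AAACTGCGGGAAAAAAACCCACTGTTCCAGTTATGCAACCCGACAATGGTGAATAGGCATGCGCGGTCAT
AGCGAAGCTCAGGCGCTGTCGGCTGAGTCACGGATCGATTGGTCCCTCACTCTGGAATTGAAAGTCAAAA
GGCACCTCTTTCGCAAGCGCTTAGTATAAGGCAAGGTAGGAGGTCGTATTCTTGGCGCGCGTTACCCGTC
GGGGGGGTATATGTTTCGAAATGTGCCTTCTACCATATGAAGTTGTACCGCCGGCCTAGCAGTAGATAGA
CTAGTTGTACAACGAACTTCCACTGGTGTCATCTTCAGGTGTATCACTGACGATGCTTTAGACGTACGTT
TGCAATTGGAGCGGTTCCTGAAGGAATTCTGGGCGCCAGGGTCGTTTTATTCGGTATTTCACCATCGTCA
TGCATTTGCACAAGGTCATTTTGGCACCTTAAGTCATTAAGTTCGGCCGG
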