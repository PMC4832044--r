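>mt_tRNA_toy1
AGAACCCACGGCTCTAACATCGGGGTTCCTTGGCTCAAAGCCAGCGTTAGTGGTAGCAGCGAAGGAGGTG
CGCATCGTATTACGGATCTAGCACTTGTAACCCATTAAGTCATTCAAAGGATTGTACGGCAACAAAGTGG
TACTGGTCCGTCGCGGCGCGTACCAGCACCCGTCGAGTCGCTTTAGATCCTTCAGGGAACGGATTGCCTC
GATATACACA
>mt_tRNA_toy2
ATCTCCACTGCTAGAGTGTGATACAAAGGCTATAAGAAGCGGTTTTGATATCGTAAGGTCTGTGGACGCC
ATTTTTGTGCGTGATTTACGCTCCCCTTTATAAACTGGCTTTTTCTATATGGTCGAGGCGACCCATCGAT
GAAATATCGAACGTGTGCCTAGAGCTCGACAATTTGCTCCCCACTATATAATAGTAGGACCTGATTCTAA
ACGACGTGCGATATCCACAGACGCACGAGA
>mt_tRNA_toy3
ACCGCGTAATATCGTGATGATCGTGCGCTCGACCCCGGAGTGTGCCGCGCGTGAAGAAACGATTCGCTAC
ACTCCCGCTTAATATCCCTGTACATTTGGTGAGGTTGTGGAGGCGCGGATCAACGACAAACGCGCGGATT
AGACGTCGGCCAAAGTCTTCACCACTGGCCTATATAGTGGTGCATTTGTCGCTTCTGGATCCTTTAAGTT
TTACCAACGACTTATCGGTCATAGGAGCCTTCCTCTGCGTGGTAGCGATG
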