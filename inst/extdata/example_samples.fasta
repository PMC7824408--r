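>queen_a synthetic COI-COII-like template
ACCACCTCTAGATCATTCACATTTTCCCAGAATGAAATTGAGGTGAACTTTTCAGAACGA
TCTGCCTGTGCCGAAACTTTCGTTTCTCGGGAACTACCAACGTTGCACATAACGGACGAT
GCGTGTATGGATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACC
GTAGTTTCCTTGTTCCTAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGA
TAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCC
ATCTACAGTTCTCAGCAACGCAGGATTTAAATCGGTCTTACCTGGTGAAGTAGTAATGAT
AGGATCTCACTTTAAATTTTTGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGA
GGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGAT
TTTAAACTACTACTAAGAAGTGCGCCCCCGAGCGGCAGAATCGCGTTTAATACAGCTGAA
CGCCGTCGAAATCTCAAACTTGCAGCTGTCACGGACGACCGAAGCGGTACCCGTAGGAAC
TAGCGGGATTAACGTTCGTATTAAGCAAGATTGCTGCTGTGATTTTGGACGATTTATCAA
AGTACAGGTTATTTGCCTCCTCCTAGTGGGTACTGGTCCATGTTCTTTCCGTGGCACGAA
AGATGTTTCGTTATTGGGGTTAGGTCATTCAAATTAACTCAGCCTTGGGGTTCTTGAATT
ATATATCTCATCGAGATCGACGGTCGCGATTTTTATTTCATTCATGAACAGTTCCATCCT
>queen_b synthetic COI-COII-like template
ACCACCTCTAGATCATTCACATTTGAATTTTCGATCTCGGCAGGGTTTTAGGGCCTCTCG
CCCGTCTATGCGAGAATTCGCTTGGTCTTCGCGATGAAGCCCGCAGTTCCAACGGACGAT
GCGTGTATGGATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACC
GTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGA
TAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTAAAACTTAAGAAGACCC
ATCTACAGTTCTCAGCAACGCAGGATTTAAATCGGTCTTACCTGGTGAAGTAGTAATGAT
AGGATCTCACTTTAAATTTTTGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGA
GGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGAT
TTTAAACTACTACTAAGAAGTGCGCCCCCGAGCGGCAGAATCGCGTTTAATACAGCTGAA
CGCCGTCGAAATCTCAAACTTGCAGCTGTCACGGACGACCGAAGCGGTACCCGTAGGAAC
TCGCGGGATTAACGTTCGTATTAAGCAAGATTGCTGCTGTGATTTTGGACGATTTATCAA
AGTACAGGTTATTTGCCTCCTCCTAGTGGGTACTGGTCCATGTTCTTTCCGTGGCACGAA
AGATGTTTCGAACTCCTCAGATTTGCATACACAAGAAGGTTTGGATCCGGAAGATACAGT
ACTCCGACTATGCTTGACAATTCTACTAGCTCCACTTTCATTCATGAACAGTTCCATCCT
>queen_c synthetic COI-COII-like template
ACCACCTCTAGATCATTCACATTTGTGTACCACAACGCGTTATAGTTGTCGCTTGTAATC
ACCGTAGCCAGAATGTACATCCTCTGACGGCCTGAACGCCACGTTTGTGGAACGGACGAT
GCGTGTATGGATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACC
GTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGA
TAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCC
ATCTACAGTTCTCAGCAACGCAGGATTTAAATCGGTCTTACCTGGTGAAGTAGTAATGAT
AGGATCTCACTTTAAATTTTTGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGA
GGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGAT
TTTAAACTACTACTAAGAAGTGCGCCCCCGAGCGGCAGAATCGCGTTTAATACAGCTGAA
CGCCGTCGAAATCTCAAACTTGCAGCTGTCACGGACGACCGAAGCGGTACCCGTAGGAAC
TAGCGGGATTAACGTTCGTATTAAGCAAGATTGCTGCTGTGATTTTGGACGATTTATCAA
AGTACAGGTTATTTGCCTCCTCCTAGTGGGTACTGGTCCATGTTCTTTCCGTGGCACGAA
AGATGTTTCGTAATGACTCATGCCCCAATACGACCCGTAGATCGTCATTGCTTGACACGA
GACGGGATAACAATACATAATAACTATACTTGAACTTTCATTCATGAACAGTTCCATCCT
>queen_d synthetic COI-COII-like template
ACCACCTCTAGATCATTCACATTTGCCAGGGCTTGATTCAGTGCTCTGTCTTAGTATCCG
CAGTAGATCCCCTGCTAACCCTCAGTCATGATGTATGCGGGAAGTCGGGTAACGGACGAT
GCGTGTATGGATAAGTGCAAGCTCAATCTACTCATATCGCATCCCCACACCACGAGGACC
GTAGTTTCCTTGTTCCGAAATAACGACTCGCATACACAGCGGCTTTCGTTGAGGGCTTGA
TAAGGGTGGTCCACGTTGATAAAATCATAGCGAAGTGATTGGTACAACTTAAGAAGACCC
ATCTACAGTTCTCAGCAACGCAGGATTTAAATCGGTCTTACCTGGTGAAGTAGTAATGAT
AGGATCTCACTTTAAATTTTTGCAATCCTCACGATCTTTATCCCTGGAGATAAGTTGGGA
GGTGCCACCAATAGCAGGGGCTTGGCGAGTGAGCTGTGAGTGACCGACGAGTGTGTCGAT
TTTAAACTACTACTAAGAAGTGCGGCCCCGAGCGGCAGAATCGCGTTTAATACAGCTGAA
CGCCGTCGAAATCTCAAACTTGCAGCTGTCACGGACGACCGAAGCGGTACCCGTAGGAAC
TAGCGGGATTAACGTTCGTATTAAGCAAGATTGCTGCTGTGATTTTGGACGATTTATCAA
AGTACAGGTTATTTGCCTCCTCCTAGTGGGTACTGGTCCATGTTCTTTCCGTGGCACGAA
AGATGTTTCGCGGACTCTTGATGTTAGCGAGCCCAGCTAACGGTGCAAGTCTCTGAGTCC
TGTTATGAAGACGCTTCTGAATCCGGCCTAATCCGGTTCATTCATGAACAGTTCCATCCT
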