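>planted_seed7
TTCAGACACCGACAGGGTAGGCTACACCCTCGGGCGCAGCACGGAACCTAGTACCATCAGGATGTGTTTA
CCAGAAACATGCTGTGATTTAATCAACTGGGGAGTCGCGGCGTTTCCTACTCGTCCATAGATTCAGTGAG
GCGCGCCGTCACGCTGGAGGTGAAGATGACGGGATGTATCCCATAGATGTCGGTGGCACGTTCGTGGATC
TGGAAGCAGCCTGGGGGCAAGGTAAGCTTACCGGATTATATTCGAGGAATTGATCTTGATCACTGTCGAC
GTGAACGCCTTATTTCCGTTGAGATATGCCTATACTAATTCCTTTCCAACGACTTGGATCAATTGTTGGG
CTCGGCGTTCTATCGGTGTTGAGTGTCTGCAGGGAGTCATTCGGGTGATGCGCTGCCTTTCTGGATCGGA
GCGTACACTGGATATATGCGCAACGTCCCTGCGTATGGCTGTGTTTTCTTTAGTATCTGCACGGTACGTC
ACTTTTCCTTTGATAACTCCGCGACTTGCTGTAAGTGTCCGAGCGCACGGTGGTTCTTCTCCTACTAGTA
AAGGTTTGTATCTCCCCAGTTCTTCCAGTGGTTCGGTTTGTAAATCCAGTGATCTCCGTGCCTGTACTGT
GGTAGTACTTGTGTTTCTTGGTTGGGAGCTTAACTCTCCGAGACACTTTGTTCTTCTTAGCTCTGCCGTC
AAGCCTACCTTGGATTGTAAGTAAAATTTGTTTCGGTCCCGGTGTAAGTTTTTTGTTTCCTGTTTGTAAT
CTTCTGAGCGTTGTTTTTTGTTTGGCGACTTGAATGTGTCAACGCGGCAAGAGGATCGGTATTCTTGCCC
CTCTAGTGCTGGTTGACATTGGCCAGCCTCGGGAATTTTTTCAATAAAGTATGGCATTCCGCCCATACGT
GGGATCTTGTCCCGGCCTAATCAGGGTTGGGGTGGACGCTAGCGGCTATGTATAGAATTTTGTCGTTACC
GGTATTTGTACGGGAGAAGAGTCCCCTACTAACTTGCTGGTACAGGAATGGTAAATATATAAGAACCCGG
CCCCACGCTAGGCCAGCCCCAAACGGGCGCTTACCAACATCAAAATTAGTACTAGTTATGTTGGTATCCG
CATCAACCGCAATAGCTCGATGCACATTCGAAACACCATCGAGAAACACGGCAACCACGTTCAGAGACCA
AGAGCCATGTCCAGCACAACTGTCGCGAACACAACCCGTTACTGCAGTCCCGGTTATATCAGGAAGCAAG
CGGTTCATCTCCTTATGTAGTAACGCCGAAGTACTCGACCATGACGAACGAATCCGAACATACAGAGGAA
AAGACAAGAGCCGAATATATGTCGGACAAAAAGACACAGAACAACTCGACGAAGCGATGAGAGACGGACC
AAAAGCATGGACCCTATTATTAGAACAACAATTAAGGTCCCTCAGAGCAGAAACCGATCTCAGAAGCTTT
CTCCTTTTCCTCCACTTATGATTCACAATGTCATTGAGAAACTGAGTCTGCTGTTACTTCCCGAACACCT
TCTACAAGAGCATTTCTAACGGTGTGCATCTTGTAAGAAAGCATGCAATTTCACAGACTCCGCGGTGCTC
AACCAGGAAGCATTTTCACCGTGGAGAGGCGGGCTCTTAATTAATCCAGCATGTTATAGAGTTCCGGGCC
GCCTGTCCAATCCAAAGGCTTCGAGCAAGGTAATAAGTCGACGGACAAGGTTTGGGTATACGCGTGTTTA
CTCTTTTATGACGGGGCATCCTGAGGCACCTAGGTATCTGTCTAGGACAGTAGGCCTACGCTTAGCTTTG
CAGCGGCTGGCGACATACGGGACCGATGGGGACGTTATAACCAATAAAAAGATTGCTCAACTAACACTAA
TGCCTTATCGGACTTTCCACCCGGTCGACCAGGCGAGTGCATGGCTTCGATACTTAACTGGCATCACCCA
AAACGCATCCCGAACATGTAAAGCCGGTCTCGTTCTCACGATAATGGTCACGGCCTCAATGACGGCGCAT
GGAAACACGCCCTACCTCCGACTTAGGCACTCACTTGCTAGGCACGCATGTGTGGACAACAACAATTCGG
AAACCTCCGTTGGTTCAAATGCAAAAATGCGAAACCGAATTAGCACGAGCAACCCCGTACTCAATGGCGT
TCAAGAGATATCACGAAGGAGACATGGCATCCTACAACAAAACCCGCCGAACAGGCCTGATGAGAATCCT
ACCAACCCCTCAAGCCGCAGCTCCTCAGTACATAACAGTTGACGTACGACGATACTACCTATCCGCAAGA
CGAGTAACAATAAATCTAGTTTACCGAGCCTACCGTCAATGGCAAAAGCCAAACGGCAGACCGGGGCACC
AGGCAGCAAGAGAAGTCAGAGAATACGTACTGGGCAAGGGCACCGCATCAGACGCCCCGAAAATAGGATG
CCCGGGGACAGGAGGACTCCGAGGAGCACCAAGATCATTAAGACCATCACTTAGCTTTGCACGGAAATCA
TTCCAGAAAGAAATCCCCGGAATAGAAGACGCAAACTGGAGATTATACTCGCCAGGAAAGTCCACCCAGC
GACAACGGGAATCAGCGGAAATCCAAAGGTTACGCGATGAAAACAGATGACGCCGACCTGCTGGAGGTTC
ATGGACGCCAAGGCTAACACCCTAGCGGGTAAGACAATCTGACTAGGACTCTCTCTTATCGACGGGTTTC
CCACCCAAGAATTTTGTGCCGACTTGTCTCTAGCCCTCGCATTCTCGGTCATTTACCCTGCGGATTTCGC
CTGGCGGGACTCGGTAAGGTCTTAGTGCGTTGTGGCTCTGATACCCATTAGTCATTGCCTTCTGCAGTCA
AATTGATAATAGTCCAACCCCGGAGACCCCGTAACATGGCACTATATTTTCATACGAGATACGAACTTTC
CAGGGCACATTCTTGTCCTATTTGGGGTAGGAGTCATTTTAAGTTGAAAGCCCCTAAACT
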