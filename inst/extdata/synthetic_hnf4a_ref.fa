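>chr20sim
AATCATTCGCGCCGTCGAATGACGGGTTTTTGAATAGCATAAAACTATCCAATTTCACCGAAATTCCAGCGGAGCGGCCT
ACTTGGAAGATTCGCACATTTTGCGAGTGACGGAACGAGTCTTGAAGGGGCGGGCGTGGAGTAAAAAAGACTATTCATAT
TTGCGATAAAGATGGATGCACATCGACATAAAGTGTGGGGGATCGATGTCGTACACCCTTGCGCAGTATCATCTCTGGGC
CAGGCTACCAAGCGGAGTTCAGGGGCGCCGGAGCTGTACTAACGAATTGCAACACTAGAAATGATGACAGGCCGGAAACC
CCGAGAAAACAACCCATGCCCCGTTTCTAGCATTAGTCCGGCCTTCCACCCCAGGTCGGTCTGGATATATAGCATCATTA
GCAAGGGCCCTGTCCTGGTGACCAGGCGCATCTATGGTATCCGGAACCCTACAGCGGCGGTAATCTCACGGGGGTATGAT
GTCTATGATCACCCGACGGGGCGAGTTACTCTCGTAATAGGAATCCTCTTGCATGTACATGAAGTGATTAAAATAATCCC
ACCCTCCACTCCTCTAATTGTTACTAAGAGACCCGAAAGAGCATTGGTTCTAGCTTATCGTATTCCCAATCATATGCGAG
CATTATCGGGGCTATCAAGCTGGGCCAGTGATCAGGAACAAGCGTTAGAGGCATTCAAGCCTGAAGCAGGAGCATCCTTC
TTACATAACCAGCTTGGGATTGTATATTACACTGAGAAGGGTCAACGTGCTGAGTTGGGAAGGATAAAAGGTATTCGTGG
CCACGCTCCAAAACAACTCAATTCCTACTTGCATACAATTAATCCGCATACCATAGTGTTAGCCGTGATTGACAATGCCC
AGGGTCCCATGGGATCACGTGTCCCACATACCCTGTTAGCGTTTTGTGTCCAGCGACCGATTTTCAACGTCAGTAGCGTG
ACGGTTTTTCTAAGACAAGGCTTGCTTACTTCATGGCAAATACCGGTTGCAGGCAACGCTCTGCGGAGCTCGGCAATTCA
CAAAGCACAGACAAGCTTAAGAACACTGATTAGTAGAAAACTTTACTTCGTCGTCCCGCCATTGTTCGATAGTGCAACTA
CCCTCGCAGAGACGTGCCTGTTCATGCCGGGGAATTACCTGTTATTCCCTGATTTACATCGATCACAAGTAGCAGCCTAG
TCGGTCTACCTCCACAAAGCTAATTGGATTTGAATACAATGCGGCATTGCGCTAGGGGTTCGCCAGAAATCGATCAGGCC
AATTTTCGTTCCGTACACGCTCGCCGATCCGTTTACTTCGCGTACGCAACACTACCGCAGTCCTGAATCCTTTCAACCTA
TGTACGAGGTAAAAGAGCGGGTTGGAGTTACATCCCCCGCGTCGACGCGATGCAACAACACTCCTAATCAACAGTTGCTC
TTAGGCACAATGACTCCCTTCCCAGGAAACTCAATGTCCGCCAGTTCCAGGGTTGCCTTAGGATTAGCACTGACGCGAAT
GCGCCTGGTGGCCCTGTTTTACCGCAGTCTTCTGACGGACTTGCGTGTAATGTACGGCTCCGGTATTCGGCGCAAAGTAC
CTTGGCCTATAGGTCTAAGGTTCGTTGTTCTATTAAGCCGAGCCAAAGGGTTACGTTACTTGACCGGTCGCGCTGCTTGT
GATCCCTCTGTGGGAGCCAGGAATAGCTTACGATACTCCCATGCGATGGAACACGCTGACAATGTTATGTCCAGACCAGC
GAAACTTCTCAGTAAGAGCTCGTGGATTGATTCCCATATTTCTGCGCCGCTCAAGAAGTTTTGTACCATTCAGATAAGGT
TGCAGAAGGCTCAACTTGTTCCCCTGTTCTAAAGAGTGCACTCGTCAGGCCAAGTCTGTTAACGAGAGTACCGATCGCAG
GTATAGGTACGTTGCCACGTGAGGACGGGGGCCTATGTATCGGACGTCGGGCGGCGTTCAGACCACCCCCCATCCTTGTG
TGGCGCCGCCTTTATGATAATCCGCTCACCTTACCGACTAAGCATACCCCAGACCAATCTTCTTGGTAGAACAGTTCTGC
AATGCAGGAAACGTGGACATATTACAACCCGCCCTATTGCTGGGCGACTAAGACACCATGTTGCCATGTGTCTGACTATA
ATTTATATACCAGAAACTGACTTGAACTACAGGCCCCATCAGGGGCCCTTCATCATGTTGGTGACCAAGAATCTATTAGC
GCTCTCTGCTTATACGACGGTGTCGTCCCGCCTTGAATTGGCGGTTGACGTTGCTAAAGCCCGGGAGTCGCATTATGAAG
TGAGGTACGTTCTACCATGGGCACTTCATGGTTTACTGTGCACGCGAGCAAGGAGTGTAGGACCACCATCGAGCTACATG
GCACTCCGATCGCTAACGTCACCTAGCAGACCTGTTGGATCGACTTTAACAGAACTATGCCATGGGCAGCTCCGAGGTAC
ATGCTCCGTGGAAGTACACCTCGTAAATAGCCCCTTAGTTGTTTACATACCTACTGTAAGGTGCAGTAGCATCCTTCAAC
AAGCCAAAGGTCGGTCAAGTACTTGCCGCGGTTTCAGCGTGCAACTTCCGGATATCACGTCGATCATTGATTTGTTGCCA
GAACACGGTATCGGGCGAAGTCCTCTCGGGGCACAAAATTGCGAATTAGGAAGACTTGAATGGGGTCGCGAAGTATGCGC
TCACTCGACCCTCTCTGCTGCTCAAGAAGATAAACGGAAGATTGTTTCAACAAAACCGCTATTGCATACGTGCTTATCCG
TAATCTTACCCCTCAACAAGTTCCCGTGTGCGAACACAACAAGTGTTCATCACTGTTTAGTAACGTTAGGGAAATGTCCG
GCTTATAGCGTTCAAACAACAAAGGGACTTATCAAAGAAAAAAGGGGTCCAGCTTACGGTGATACATTAGGCTCCGCTCA
GAAACCGAATTGCCACGCTCTCGTTTTAGTGTTATATGAACAACCAGAACGATCGCAGGAAGCGCCTGTCGAGGCAACCA
ATCCCTTCGATGCAACCCGTGTCATCCTAGAGCGATTACGAGCGCATTGGAATCTCTTCGGTTCAACTAGTGGTTACGTT
CCCGGTAGGAAGCCAACTCCTTCGTCAAATGAACATACCGCTGCACCACGAAATACCAGTCTACACCAGCATTTCGCGGA
CTCATGCTCATGCAGAGAATCGGGGTTTCTTCATACCTGCCCGGTAAACCTTCCACCTGCGGAGAAGTATCTGGACACTG
TCGGACTTACTGCTTTACGGCGTAACCCTAGATACATCCCGTCGCATGTGCTTTTGAAAGTTGAGATCGGCCGTGTGAGA
ATCGGCTGTCTTGATTGCATACCAACGTTATCCCTTTGGGCACCAGCAGTTAAAACTCAGTCCCTGCAGACAAGCCAAGT
GCAGAACCGGAATCACGCACCGCTAACCTTTAGGGCCCTACATTGTCCGAATATAATTGATCCGATACATGAGGGCTGGT
AACGGCTTGCCAAGGAAGTCCCCCCAAGGTTCTGTCGTGTACACAGTAACCCTCACATTATCGTACAGATGTCGGTCTAA
GCGGATCCCGCGCCCGAAGGTCATCCACTCAAAACATTGCGAAAACGGCCGCATCTTTAACTGACGACAAGACCAGCTAA
TAGGTCACGGTGACCATTAGTCCGTAAAGATCCGCTGCTCCTGATGGTCCCGATAATGACTATATGTTAGTATCGGCAAA
CTATTATCCACATCACTCTCAGCCACGAGAGCAGTATAAGATGCCGTTGGTTACAGGGCTGTTCCCGCTGTTCGCCAGCA
AGTTCGCCCTTGCTGGCCTGGGCCCAGTTACCATTCCGCTAGCCCGCTACCCGGAGCGGTCCCTGACGCATT
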