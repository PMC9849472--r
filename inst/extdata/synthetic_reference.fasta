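>synthetic_rCRS_regions_8001-9000_9801-10900_16051-16400
CAAGATTGATAGGAAGAGTACTAGGTATTCATAGTGCTTCATGGAATCAAGTGATAATAAACTGCAGAAGCACTCATCTACTAGGAAAATAATGACTTTAGCCACGCACAGTCCACCGTTTTACATGACTCGGTAATTTTTTGGCTCCCAATTGAGGACGGGACCGGGTCTTCTCGCTATCAACTCCACCCTCCCGATAGGCATACGAGAATTCCGGCTCTTTCTATACGAACCTCGGTAGTCATCGACGAACCTGTGAGCAACCGGTTAAGGCTACCTTACCGATTTTCCTTGTTCTCAAGCAATCTCCCGAACAGCCTGCGTAGATTCTCCAGGCCAAGGGGCTCGGTTGACTCAGTGAAACCTTCGACTGTAACTCTGAAACAACTCGCCTCGAACGACAGTCGAGCAGCTCTGCGGATACCAGAAGTCCCCATTTTGGTACGCTCGTCTTTGTGTCACGTCCCAGTCTACATCAGTACAGTCACATGGTCCTGGACGGTACAGCGCTCAAATCATGAACCCCGCATCGAAAAATTCTCGTGGCACCACGTTCCGTAACTAGTTCAGAGTAACGCGTGGTCTCGTGGCGACAAACAACACCTTAGACCTTGTCCGAATCTTGCTATGCTCATTCGGACATTAATCCCTGAACGCAATTCTATCGATGGTCACGTCAGGGCACAAACGCTGCTGGTTACACTATCGTAATTTCTAACCGGCTTCGGAGTTTAATTTACAAGTGGCCCGATCATCTAACCATCGCAAGGGCCCGGTCAACTTGTAGGATCAAATTCGCCCGACAGTGTTACGCGTGGTATCGATGTACACCGTTAGTATTCAATAGTGGCCAACCGTACAGCGTCGCTCTCGATGTCCGCCTAGTTATCGTTGCGGTGTGAATCAGCAGGCCCTGCGATTAATTATAATACACCACTTCGGGTGGGGCTCTCCAAGTACTACAAGAGGTTTGCTTCAGGACCAGCTTGGGTAGAGGCACCTTTCCGTTAATAGAGGAAGCTACGGGCCATAGTCAATCAGCTTGGCGTAAGTTCATGCCCGGTCTTGCACGGGCACGCTTCTGACCGGATAAAGATATAAAATGGACAAAATACTGCACTAATCCCTCCTTCTTATTTGCGGTCGCGCCCGTCGGTCAGTAGTTAGATCATGGTGGCGAAATGTGGATTCGGAACATCGTCTGTCCGGCACGCGCGAACTGTGGTGCACGATGGTTCCAGAAGAAGTACCAAAAAGCAGCATAGGCTGCATTTTTCCGACGGAAACTACCACTTAACGGAACCGAAAGTGAGAATTACACGGTCTAACGATTCATCGCGAGTGGGAATAAGCCTACTTTCTCAGTACGACGCCTCAAAATTAAATTTCTCAGCTTTTCCGGGTTCATACATCGACCGGTCTTGCTCTTCGCCTTAAGCGCGCCCGGACAGCGCGCGGGAGGCCTGCGCCCCTCTGCAACGGGGTTACAATCGCCGAATCTCTTTTCATTGACTGACCGCCGTGGACATTGACTTAAACTACGGTGGGCACGGCGCTATGCACCCTTGACAGTGCAGCCGAGTGAAGCCAATTGCACGCGTGGCCACAGGCTGTAAAAAGGCAGCCGCCTAATACAAGAGATCAGTGTGCCGCTTGAAATATGCGAGGGAATTACCACCCACGTGACGACATGTAGCTAGGTAGGGCACCCAAAATATGGTAGCGGCTGTATTTAACGGGGGGTGGTTACATGCAGCATTTGTCCGTTTTAACTACCTCTTCAAAAGTCAAGTTGCTCCCAAGGGAAGGCGCCAACGTAAATAGAAAACTGGTAGAGACGGTTACGAGATACTCGAGATCAACGTATGAGGGCCACTCCCGTTCCTACTCGCATGGAGTGAGAGCATGAGTGTTCGACTCAGTGCTCGTTTGAGACGACTTACACGGCGCGAAATAAGCTATGTGCAGGGAATCGCGGTTCGTACCGGCTCTGCTAAACTTCAGAATTATCGCAGCGATAATCCTGCTAGTGAGTCCCCGACACTTACCGTGCCTGAGCCCCGACAGGTTGCGTTACTAAACCAGAGGGTAGAAAGTGAGTTGTGCCTATACAAGAATTTCAGAGCGAGCGAAAGAGAGTAGTTTCGCGGACCTCTGCGGTTCTTGTGAAGCTGCAACGCAAACACTAAGTGGTATCCATTGCAGACATTGCCATTCTTTGGGGGTACGATCAGGTTTATGATTCAATTAGTCGTTTACATTCTTGGGAGCCTGAGGAATAACTCTAATCGTAGTGCCGCCGCATGCTCTATACTACGCATACAATACCCCGCTCGTTGATCTACTTTATCTTGATCACTACCTCTATATATCACTCTGTTGGCAAAGTAGGGGGGCAGAGTACGAAAATGGAACTTAGTCTGTGCTAGCGTATCCGGTCTACGAATCTC
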