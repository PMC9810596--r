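>synthetic_mtDNA
AGTCCATGGCACATAGCCCAGGCGTTAAAATTAGTCCACACGGACGCCAATTCACTCAGTGGGAATTTTCAGTGCCATCA
CTTGTTTACTACGATCAACCCCTTGCAAGCGCACCTGCCAGCTATCTTCATGGGTCAGGTATCTATGCAAACGTTAAGAC
CGCTCGTATCCTATGACTGAAGGAATTCGGGTTGTCCAATATCGACGCGCACTTCGAGTCGAAGTTCTCCGAATATTGCG
TCTAACCGGTATGAAGTACAGGACGTTGGATGGGCAGTCCGGTTGCCGTTGTGTGCGCAACCCTTGTGGACAACTTCGGT
GTCCGCGACGGAGGCCGATGGTGTGTTGCTTATAAGCAGCACTGAATGATGCAATTAGAGCGCTCCAAGTGTCCGCTTCC
GTATGCAAAACATAAAGATCGTTTGCCATGATCCCCTGATGTGGTAGTTCCGACGTGTAAATTGACTGGCGGGCGAAGTT
CAATCCTCTTGAAGTCACCAGTTAGCCCTCTGATGGTTGTAACCTCCATCCCCGGGTATCCGACGACTTGGTCGATTTAG
TTACAGTCATGGACACTTTTAGCCACTTGTGTTTTTACGCATGAAATCGAATGTGCGATCCGCACTGGTGGCATGTCGAT
GATAATATGATAATCCCGGGGAGCGAATCGCGACTTTGAATGCCTGGCGGCAGTACAGAAAACGGGCCGGACCAACCTTG
ATCGCAGGATTGGTATTTCGGGACAGGCCTAGAGAGCTTGACATGTGATCCATACGTTGGTCCATATGCAATTAAACAGC
ATGCCCTATTGTGCTTAACGTTCGCGAAACTGTGGGGCACGGTAGACTGGCATTTCCAGAGTCATAAAATTCTTCTCCCG
TCACAAAAATTACCAACAGGAGAGTCTTTCGCACGAGCTATTGCGAGTAGTCGACAGAATCTGGCACTAGCTGGTGGCTC
GCGTCTAGTAATATCTATTGGATCACTATCGGGGTTAAACCCACGCTGACCCTGGAGATCCGTGGTCATGCGCTATACGC
CTGATATGGGCATAGCGGTGCCACTTTGATTATCTAAAGCCATGGGCGCTCGTCTGGGTGGTCACGGAGCTAAGATGGTC
CCGGATTTTAGCGGGTGAGTACTCCCCCTAGCATCGTTAATGTGTCGCTTCGATCTCCAAGCTATCGCGCTCTGATGGTC
GACCCTGCATTCGGCTCGCCAATTGAATGATCGCACTCAATCATGGAATGCTTAATGTTCGAGGCTGCTTTCGTTATATG
CGAATTTGAATGTACCTGGTGCCGTTGGCTGTCATACCCGGATTAGCTGCAGTCGCGTACTTAGTCCACGGATGTTATTC
TTTACGTGGACTCCCTTTCCATGCGGAGTTGCCGTAAGCAAATGGAAACTAAGTTTTAATAATTCCTCCGGATCGTATTT
AGCTAAGGATCATGACTTCTGAATCTTAAGCGTCGTTTCGCGCCCAGGGCCAGACACGTGTCTGTTAGGCTTCGCTGTTT
ATGTGGCTGATAGTTCTGTACCTCCCCAGTGTGTACTACAGGATTTTGGGTTATATGCAGAACACGTCCACATCCCTTTA
AATGAACCACAATACGAACACTCTGGTAGGTCGATACTTTTTGGGTCCGGCATGAGCAGCTTCTATCTGGCCGGAGGTGA
ATTTTGGGCGTTCCAATGCGGTATGGAACAAGCCTAACTTCCAGAGCACTAAGATGCCGGGGACGACACACCTGATGGAA
AAGCTAACACCATGGACGGTCCACCTTTACAAAAACTTTGCATACTGTGCACTGGAGAGCAATCGTACGGGTCGTGGTTG
TGGGCGCTGGACCTATGGGCATACATTTACGACTTCGTACTTGTTTTGCGGCTGGAAAAGAAATTGCCACGATCTCCTCT
TCGGCACTAGGCGTTCCTGCCGTCCTGGCCCTTGCATTATGTATTCTGTATACGAAATTGGATGGTTCTTATGCGAGAAC
GATGACGTGTCGCGCAACGTCGGGCGTAACCGGTACCGCCTTTGTGACTGGAGCTCGCCGTGCTACGAAGGTGTTAGAAC
ACCACATAACCCAGTACCTATGCTAAAGCGCATCCACAAAGATGGGGAGCCTTTCCTCGGTTACACCCCTCGAGCTTACG
GGTCGAATTTTAACTCGGAGCTCGGACAGTTCCAGCAGGGTACTTGTATCATCACGTCCCAACTTGATATGTCATTCATT
ATGGACCTGACTTTCCGTAACGGGGAAAGCTTCCAAACACCAATGTTATTTGTGTGGGGCCCCCATGTTAATATACGCGG
GCCAGGAGGCATTCTTGATCAAGTTGAGAACCTTTTTCTAGCCAAAACTGGAGGCATTAAGGCCCACGCTGAAAGTCAAG
TCTTGAATATCACAGCCCGCGTTCTTAGTTCATCAGAGGCCATTGCTATGTTCAGCTCGCGTGTTCTGCCTACAGGGCGA
GGATTCTGAAAAAGGCCAGCCCGGTTGTCTCATTTGCCCCGGTTTATGTAGTGTACGAGGTCATGCAGGATTTATATATG
ATGTACGGGCGCGCTCACACTTGTCGCCCTTGTGGTGGTTATGTGCACACGTATGGGGGTGCTTCGGTTGTCCCACGCAT
TGACGTTAAAACACGCTCCATATCAATAGGTTTGTTTGCGATTTGCAGCAATCACGCGTCCATTGAAGAAGGCGTTGTGG
GCGCCTATGAAGACCTTCTAATCAGCCCCAGTCAGTTACGATGATGGCCATGTGCTACCGTTCTTGGCGAAGACTTTTCT
TGAAGCCGTTATTGCCGCATTCCTTTTCGAATCAGTCGCGGAATCACTGGAGTTCCGTATAGTTGGGGACTACCCGGTAG
TGCGCGTCTAAACAAAGTCTAATAACTGACGCCCTTCCGAATTTAGTGCTCCTCCGACTGGCTAGCAAGAAGAGCTGAGG
AACCAGCGGCTGAGCCACAGTGGAATGGGACGCAGCGTCAGTGCGCTCTACACTTACTCGAGCTATACGTGGCACGTGCG
GCAGAACTTCTGTCACAGATAAAATCTCTCGGGTGCGGCGCTGAACTCCCAGATAGGAGCGCCACGTCATCGAACATTTT
AAGAGTACCAGTCGATGGTCAAGATTTCTGTTAACGGACTGGGACCAGATGCACCAGACTCCTCTTCGATGGGCACCGTT
GGCGTTGGCGGGGGGGCTACGAACATGTCTAAGTGGTCCCCATTGATCTCGGTCCTTATTAGTGACTGGCATTGGCGCGA
GCTTTGGTCACTCGTGCAGAAGCTACCACCGGAAGGGTTTCGAGCGCGCCCCTGTCAGTACTGGGGGCACTTGGTAATCT
CCGTCAGCACCACCTCTTCTTTATATAGTTGTACCACTAGCCAAGGAGTATGTCTGGTTGCACCCTGGTCCTAGGGATTT
TAACTATACGCACGCGCCGTCTTGATGACGCCCGATTGCCGTTGCAAGGTGCCTACCCACGGTTGGGTTCCGCGTGCCAC
GCTACAACAGACACGGGCTCAGTATGCACCGACT
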