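>MytA_1
GGTGGGGAAGTGCAAATGGACTGGCGCACCATAAAAGTTCCCCCAGCACACGCATCATTCATAAATGGCA
ACCCTATGGCACAAATGTGCTTCATGGGTTACAAGTGCACAAGGTGGGCGGACTGTTCGATGGTGCCGTG
CTATGTTTCTTGTAAGCGCGAACATTGCTCAGAGTGTATCATAGACTGC
>MytA_2
TGTTCGATGGTGCCGTGCTATGTTTCTTGTAAGCGCGAACATTGCTCAGAGTGTATCATAGACTGCCGTT
TTGGCGATGATGCAGCAGAAATGTTCTTCAATTGGGTACAACAATTTGACCACCAAAAACACGTTAGATG
GTGGTACAATACATCAATGGACTCGGCTGAGTACATGTTTTAATTCAGTCTTGTG
>MytB_1
TTCCTTGTGTGTGGCATGCAAGTGCCGCCACACCAGACCGGAGTAGAGTCTGCGAACGATGTCAATGCCA
TGAAGCACCATACCTGGTGCGTGTTATGGGCTCCGTGCGAGGGAATCGAGAAATGTCATGAACATACTTG
TGACAAGATGTGCATGTTTCCTGCTTGTCCTTCATGTATGCTGGACTGCAACACAGAACAAGACTTCACG
TTCCATAAAATTCTGCACACGGAATACATTTGGGAAGAATGGGATCATATGAAAAGCGACCATTTCGGAC
ATGTGTATACGCAGCAAGTATTCTAACAGTTCTCCTGT
>MytC_1
GAGTAGAAATATGGAATGAAAATGTTGCATTCTGTTAGGATCCAACACTCAGAAATGATGAACATGCACC
TTCACATGTATCATTACTGTACAGATCTGATGTATTGTGACCAATACTGGTATTGTAAATTGGTGGGGTG
TGTCTATCGTTGTATGTATGTATACTGCGACTTCTGTGGCTATTTCTGCTGGGCC
>MytC_2
GGGGTGTGTCTATCGTTGTATGTATGTATACTGCGACTTCTGTGGCTATTTCTGCTGGGCCAATATGTGG
AACTTCCAAATGCAAACCTGGATTTTTCGTGCATATAAGTACCCAGTCTGGTGGGAAATTATGTATGCCT
GGGATAGTGAGCAGGAAATCGTTAGTCCCTACCCTATGATGTAATCCGAATTGGGC
>MytlB_1
CGTTGGTCCTGAAAAATGATCTCCGTTAATATTACAAATCATGAGATGGCCTTAACGATAGTCCATTCGC
AGATCTTTAACATTGTAGAGTGCGGCCGAAAAAGCTGCGGGGCCATGTTCTGCCTTTTTTGGTGTGGCAA
AAATTGCCGAAACACTTGCTGGGTGTGCCACTTTTGGTGCAACATG
>MytlB_2
TGCTGGGTGTGCCACTTTTGGTGCAACATGATGTTAATAAATATGCACGAGCATCACCAATATATGATGG
AATACCCTGACGGCATGGGGATACGAGACTGGCATCCTAAAGGAACAGAGGGTACCTGGCCTCTCAGGTT
AATTCGAATGGTCTTCTTAGTGATGCTGTAATCGTTTTGG
>MytlC_1
CCTAGAGCATATTCCATGCCAGGACCTGGGGTTGATTGGATACCGCATATCAGACATGATGACTGGAGCG
TCGGGGGGACCTACCCGGTCTGTATCACAGTTGTTTGCGAAGGTATAGAATGTAGTAACTATTGTAATTA
CATGTGTATAGAGTATTGCGACGTCTGTTTGCATATT
>MytlC_2
ATAGAGTATTGCGACGTCTGTTTGCATATTTGCTTTCGAATGGAGCCAGATATGGGACCGCACCATAAAC
CAAATTGGGTTATGTACAAGGGTCATTCGGAATCCCCTAACTCTATCATGACCAACGTGCATGAGCACGT
AATGCAGACCAAATTTGTTGATTTCCCGTAAGTTATGTGG
>MytlD_1
TGTTCTTTCGGCATTATGCACAATCCTATGCCAACGAGACATGATCAATCACAAAAAGTTCGTTTCATCG
TGCATTACGAAGAGAAGAAGTGTGCTATTCCTAAATGTCGGATGCATAAATGTAGGGCTGAATGCCCGAT
GATTTGCAGCCCGCACTGCAACCGGTGCTTCCACATATGTCTGAATCCTCATATGCCGTTCGACCCAAAC
ACCGATACGGACAAATACCAAATAAAACGGAACTGGCGAATTATGCCCTATGGAGATAATGCTGATAAAG
TTGTAATTATCCCCGGCGACAGTTATTAATCCGCAGCGAGG
>MytM_1
TTGCAAAAATATATAGTTTTACGGAACCACGATCGTTCCTGTCAGCCGATATGCAATAACGAAGCCTGCA
TGATGTGGCCCTGCGACACACGATGTTATCATGCCTCATGTAACTACCAGAACTGTATGCTCGTATGTTT
CGTCGTATCCTGCGAACTGCCGTGCGGTGTTGACTGTCATAACTGGTGCGCACCGCCGGTCAGAGAGTTG
AGGGAACATTTCGCCCCCGACGCCCGGACTTTATACGCTAACGTAGATGAGGAGCTACACTGGCTAGGCG
TGGTTTCAGAGTTCGCAGGCCGTCGAATTCTGGATATAATGAACCAATCGCGTCGCTGGAGTCGCGACCA
TGAAACCATTGAACACTCCACAGTACCTATGAGATGGTGGGGTGATCATAAGGACGGGCCGGCGTCGGGG
TAATACTGGAAACAA
>MGD1_1
ATGACGTCCAAGGGGGACTACCATAAAGCGGTTCACGGATTTAATACTAACTATAAGCTCTCGGTTGAGT
GCCATCAACATAAATGTCAGGAACCAGTCTGCCCGATCATTTTCTGTCAGCAACGAGTCTGTTGGTCGCC
TGACTGCGTGGGAGCTTGCCCGATGACTTGTATGGAGTACACCGAGAAGTGGGAGTTAATGCACAGGATG
TGGCAGCACAAACTGAGGTTCGACAATCAAACTTAATTTCGATCATGC
>MGDt_1
TAAATTCAGGCGGTAATGAAAAACCAGCCCGGCATCGCTACTCCTAGTCATGGTGGAAAATTTTGGGCTA
TTTTTGCCGTAGGAGTTATCGCCTGCTCAATAAATCTCTGTTCTTACCAATATTGTGGTTATCCCACTTG
TGGTCAACCCAAATGCAAAGCAAATTTCTGCAATAGCCCATGTGTCGATGAGTGCAAATAAGAGGTGTAT
AAG
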