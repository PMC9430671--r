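>G0001
ATGCACTATTCGGTTAGTCTAGCCTCCTTCCGGTTCGCCCCGGTCCTGCGGTTGACGTATAAGGGGCATCGGGCAAATGA
ACCGCTGTACCTAGTCACGGAAGGACACTGCATAACGCGAGTTGGGTCCAGATTCGGCGTTTCAGCTTTGGACCCACTCT
ACTCGCCCATCGACGATTCCCTAAATGTCACTCGGGAGTATCTCATCCTCAGGGCCGATAGGGCATTAGCCAGGGACATA
AAGGCTCTTCACCATCCTGAAACACCTCTGTCACTCGAACTCGGTCTGCAGGCCCTACTCTCGACTAGATACGCTCTGGA
ACGCTCGTCATTGGACAGATGGCGGAATGTATGTCAAGATTTATGGATAACGGATGGAAGAACCCTATCATTTTTGCGGA
CACGGGTCACACGCCAGTTGCGTCGCGCAATTCGAACCAAAGATGACGCGGTGACTACAATTATAATCTGGCGTTCGGAT
TACCAGGGCAGCTTCTGTGGGTCCTGGTCTATGCTTACTGAAGCGGAATATTGCTGTTTTGTCATGATACTCACCTGGGC
AGGATACCATGCGATGCCAGTAGCACTTTTGAGACACCCAAACAGAAGTCACGTCGCGTCCGGTGTCGGAGTACTATTTA
TAAAACTATTGCGAGTGATTCACGCTATGCACCTACACGGTATCGTTGGCCGACAGATCAGTCCTTGGCCTGTCAAAGGC
ATTGGGCTACGAGACGTGACCGCGCAGCCTGATCTACCATGTGAGCATCGCTCAACCATAACTGACATCACGTTAGGACT
GTACTTGGCTCCAGTCTCGTTATATCTGGGGTTCCGCAAAAAAGCGACAGGCCCAGTCCTATTTTGTCGGGCTCTTATTC
TTACTTCTAACGGGCGACTCGCCATCGAAGCCTAA
>G0002
ATGCATTTGCCTGATTGTGCCCCGGAACGCACCCGACCCATCCCGCGCCCTGCCAGTGTGGCGTGTGTCTGCAACTTACT
AATCAGGGTTCGTCCCTCCGTGATGCAATGGACGTCTACAACGATTATGCACCATAAGGGATCGGCCGGCAGTGACACGT
TGCATCTTCTAGTTAGTTCCTCCGGCTTGCAAGCGCTGGCAAGGCCCGTCTGGCGCTCGATTCAGTGGAGCATCCCATTC
CGTACTAGCCGCATTCGGAGTTATTCGAACACTATAAAAGCAGCGAAATTTCGTCGAGCAGAGTCGCCTAACGGCTGTGA
AGTTCGGAGCCTGCTACGACAGAATAAGAGTAATACAATGTCTCGGACGTTAATAAATCACCCCAGGCATCTGAAGCATC
TTTTCACGCAGGCTCCGCTTTGGGCACAAGGGGCGCACTTCGGGACCGCTCAACGTTGTGTTCGGACCCAAGACTGTCTC
TCTTTCGTGTCGCAGTTGGGGTACGCTCCGCACATCGTGGGTTCACGTAAATCAAGCCCATGCTGCATTAGAGGTGCTAC
TTATCCGTGCCCATCATACACAACATCCTCCAGAACTTGTAGAGGAGGAACACAAATGGAGTGGCGCTGGCATGTTTCAT
ATTCCCTCCTAACGTCACCGTTGGGGAGCCCTACCGTACCCTCAAAGGTAAAGTACTTGAGGGTCCCTCTTCAATCCCAA
CGCCTTTCGGTCGAGTTTGTTTGGCATGGCGTGGTAATGCAACGCCCTGATGGGACATCACTGACCAATTTTATACAGAG
TATCCTTATGCTGCGTCAAACACACAATTGCCAGCTTAGAACTTCGGGCCGTTCTTAA
>G0003
ATGTCCAGCTACCGGACCTACGATCGGTTTACGAGAGTAGAGTATCGACCGATTGAGGACTGCTTGAGATGCGCTTGCTC
GTTGATCGAAGCCCATTCCTCGTCCCAAATTCGTGGGACACTGTTAGCCCAAATTCGATCCTTTCCGCCCCCTGTTTCGG
GTACCATGCCCCCTGAGTTTGAGGTGATATGTCTACGGTCGGCCTGGCCTCTGGCGGCGCCGATTGGGTATACGTTTTCC
TGGGCACCGGTACCACTCCGTTTGGCGATCGCCATTGCAGCCTCTAGGGGAGCACCGGTAAAGCGTCTGCCCTCGAGGTT
CCCACTAACGAGAAACGACTGGAACTACCAGCCATGGACGCCACACCCGTATGTTCTAAACACGGAACTAAAGTCCGTAG
CGCTGGGGCTCTCGAGCCCGTATTTTTCGCAGACTTTACCTATGCATGGATATTGTTGCCGAGCCGTTAGATATAAACGG
TCAGACCACTCCCGCGGTAGACGGAGACATGACGCGCACCATCTGGTGAGCATTCCCACCTATCTGCTTAGACCGAAAGC
GGCTTTGTGCAAAATCATGCACAAAGAAACGCGTCATCGTTGTGTTCCCTATAACATTCATTTCAAGCGCCTAATACAGT
CTATCAGGGGTACTACACATAGCTATGCGATTCGAAATTACTGCCCCAAAACTCCAGCCAACATCCCGAGCATAGACGGC
ACCCGTCTCCATCGACGATTAGTCAGTATCCGCGATCTAACCGGTGCGAGTCCCGCCGTGTACTCAAGTCAGAGTAATGT
GGAAGCTGATTACAAGTTGGCCCGCATGTGGGACGGTGTTACTGCACGAACCCTGGGCCGCCGCACGTCCACAAAGATAG
TGGATGAATCATCGGGCGTAGGGAGCGACCAGATACAACTGCGAAATTCCTCCCGACCTTTCTGTAACAAGCGATGCACC
CGAGTAAATTGTCGCCGAGAACCAGCTTTCTTTCTGTACAGATCGACCGATAAGGATTACGCCTCGATGGTGCCCGTCCC
TCTAGCTAGACATGGACGTAAAGTCGATGTAATGTTTATAATCACTCTTAGCACGCAGCTCCTGTCACGATAA
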