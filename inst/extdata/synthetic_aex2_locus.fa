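>synth_chrX
AAGAACGTTGTATTTGAATTTGGATGCGGCCGGATACTTAAAAATACCACGGATCTGGATTGCTGATTAG
TGGTGGATAGCCGCCAAGCTCTGAACAGGCTAAGATAGCAGTTTGTATGAGCTGGCTAAATATGTCCTTA
AGCAAGTTATAATCTTTAACTTCTGAACATTAGTATCCATGTAAGTTATCCTTCACTCTTCTAAAATGAA
GATTCTTAGCTTTGAGTAGTATTCTGCATGGCCTGACAAGAGAGATTGACTACGTAATTTATTAGATTTC
ATATTAGCAATAGTTTGCTACTAAAAATTCAACAAGCTAGTAGTGAGGTTTCCTACCCTATAGTCGAAGT
TTAATTGGTGATGGATGCGTCAAAAACATATCTTACGCAATTTACTAGATCTACCTATTGACAGGCGGAT
CAAACAATGTGTTAAATTACTGGCTTTATGCGGTTGGTTCAGTGCCGTAAACATGGGAAAGATGTCCTTC
TGTGTGTTATATGGCTAGACCTCTTGTTCGGCTATGGATTGTGCACGTGATACTAAGAGGAGGAACTGGT
TATACATTTCATTTCAATTTCACAATGATAATATGAATGGTTTATTCATATTTGAGCCTAGTATTTAGTC
TTCAACGAAACGATAAGTGCCAGCCATCTGCCCGGCCTTGCTGTGTATGACTTCGTACTGCCGTGTAAAC
GTAACCCAGTCTGCCGACATACAAGACTGAGGGCCGATTCCTGTCCTGGCTACAGGCGCCGCGTCGCGAT
ACTACTAAGAAACGAACTGGAATTCTTGTGTCTAAAGAAACAGCAGAAATAGGTGCCCTCCCAGTTCTGG
GCATCTATTTCGGGTCAAACATTCTGCTACCAATCGCCCGGGTCATTACTGCAGCGACATGGGGTGGGAT
CGCCTGAGGTTCATGCTAGCCCATATTTCAGGGGCACCTACGCTTGGTTTCGGAACCAATGTCGTAATTT
TAGATATATATTTTTACTTATGGAAAGGAGTATACCGATTACGATCTTGATTTTTTAGCATCGCTCTCGA
AGTTGCGCTGGGCGCAGCCTGGCCGCCGACGGAACCCGATTTCGTTGTTCCAGCAAAAATGGTGCGACAC
AGCGATAGACGAGGAGTGCCTGACCTTCTACTGTGGGCCTCACTAACGGTGAGAAATAATCATCCCGACT
ATTATTCGCATTCGCGGAAATAGCACCGTACGCTATCATTTTTCACTATAATGGCCTGCCACCCCTTTTT
GGGGATGAAGTTTCAGCGCTTAAGTTAGCCGCCTCCAAACGTACGGTGCACGTTAAGCCCGCATGCTTTA
CCTTAAGTATACAGAATGAATTTTTAATCGTAAAAGAATCATTGTGGTAAAATGCTATCTCGGGACCTAA
GAGACTTGGGACAAGACAAGATTGCCGTCAAGCACGTAATCACCTCTGCTAAAGTGAGACGGTAATATCA
TAAGAAAAGGAAGGCTCATTATGGAATATTATGGAATCTGAATAAATATCCATCTGTTTAAGCACAAAGT
GCTTCGTGTGACAATGTTAAATCAAATCTAACACAAGACTCGATTGGTTCGTGCACAGATTTGTTTTTAA
TGAGGGAACGAACCAACATAGTCCTTTAGTCTAGGAGCATAGATACACTTTGAAACATTTTACTGGACAA
ATGGTGGCTTTTTAATTTGACTTATGAAAAGGAAAAGGTGCAGTCTTCCTTACGGACATCTTGCTATGGC
TATTGGCCTTGATATACGAACGAGAGAGCACATCGAAAGTGAGCCCCAACTACCTGTTTGTTGGCACAGT
ATACTGTAAGCCCTGCTCTAAATAAATATAATATTATTTATTCCAGCGGATCCAATTACATAAGAAGCGC
TCTTTAAATGATTTTCTAAACTTGGCACAGAAGAGTATCACTTTCCCACAATGTGAAACTGTCGTTAACT
GAATC
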