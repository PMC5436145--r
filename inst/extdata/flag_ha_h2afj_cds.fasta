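>Flag-HA-H2AFJ sh2-resistant coding sequence
ATGGACTACAAGGACGACGATGACAAGCTCGATGGAGGATACCCCTACGACGTGCCCGAC
TACGCCGGAGGAATGTCCGGTCGCGGGAAACAGGGCGGCAAAGTGCGAGCAAAGGCCAAA
TCCCGCTCCTCCCGCGCGGGCCTGCAGTTCCCGGTGGGCCGAGTGCACAGACTGCTGCGC
AAAGGGAACTACGCGGAGCGAGTGGGCGCCGGGGCGCCGGTGTACCTGGCGGCGGTGTTG
GAGTACCTTACGGCGGAGATCCTGGAGCTGGCTGGCAACGCTGCCAGGGATAATAAAAAA
ACCAGGATAATTCCCCGCCACCTGCAGCTCGCCATCCGCAACGACGAGGAGTTAAACAAG
CTGCTGGGCAAAGTGACCATCGCTCAGGGCGGCGTCCTGCCCAACATCCAGGCCGTGCTG
CTGCCCAAGAAGACGGAGAGTCAGAAGACGAAGAGCAAATGA
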