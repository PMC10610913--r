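>aSyn_P37840_synthetic_cds representative reverse-translation of UniProt P37840
ATGGATGTTTTTATGAAAGGTCTTTCTAAAGCTAAAGAAGGTGTTGTTGCTGCTGCTGAA
AAAACTAAACAAGGTGTTGCTGAAGCTGCTGGTAAAACTAAAGAAGGTGTTCTTTATGTT
GGTTCTAAAACTAAAGAAGGTGTTGTTCATGGTGTTGCTACTGTTGCTGAAAAAACTAAA
GAACAAGTTACTAATGTTGGTGGTGCTGTTGTTACTGGTGTTACTGCTGTTGCTCAAAAA
ACTGTTGAAGGTGCTGGTTCTATTGCTGCTGCTACTGGTTTTGTTAAAAAAGATCAACTT
GGTAAAAATGAAGAAGGTGCTCCTCAAGAAGGTATTCTTGAAGATATGCCTGTTGATCCT
GATAATGAAGCTTATGAAATGCCTTCTGAAGAAGGTTATCAAGATTATGAACCTGAAGCT
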