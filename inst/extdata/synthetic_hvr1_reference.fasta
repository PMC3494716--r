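>synthetic_hvr1_reference 16051-16400 (synthetic stand-in segment, not rCRS)
CGACTACATCATCAAGCGGACCGATGTTCAAATATTTAATCAGGACATTCTCAATACTTGCAGCAGGGGC
TGTTCTCCGTCTGACCAATGAACTACGATTGACGGCCAAGCCGGCGGTTTCTAACAATTGAGTCGTTGTG
AGAAAAACACATGTCTTGCGGAATCGCGTCGACCAACACCCATATCAAAGCAGGGTTAATTGATTGGAGG
ACGTTATGTGGTAACCTACGTTAATCCGGTCTCACCTTTAAAGTCCATTAATCTTATATATATTTCCACA
TGCACTCGGATTGTTAGGAAGTTCATACGCGTTTCGCCGACGTTTATAAAACTTCTCCATGCTGGTGAGC
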