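LOCUS       SYNCON1           155 bp    DNA     linear   UNA
DEFINITION  synthetic expression unit, constructed fixture
FEATURES             Location/Qualifiers
     source          1..155
                     /organism="synthetic DNA construct"
     promoter        1..35
                     /label="pSyn"
     RBS             36..53
                     /label="rbsSyn"
     CDS             54..104
                     /label="sfgfp"
     terminator      105..155
                     /label="termSyn"
     misc_feature    complement(36..53)
                     /label="rev_mark"
     primer_bind     join(1..10,20..30)
                     /label="split_primer"
ORIGIN
        1 ttgacagcta gctcagtcct aggtataatg ctagcaaaga ggagaaatac tagatggtga
       61 gcaagggcga ggagctgttc accggggtgg tgcccatcct ggtcccaggc atcaaataaa
      121 acgaaaggct cagtcgaaag actgggcctt tcgtt
//
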