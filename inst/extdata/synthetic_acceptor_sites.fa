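>synthetic_acceptor_001
ACTCTCTCTCTCTTTCCTAGGCG
>synthetic_acceptor_002
TTTTTTCTTTTCTCCCTTAGTCC
>synthetic_acceptor_003
TTTCTTTTTGCGGTTTTGAGGCC
>synthetic_acceptor_004
CCTTCCCCCATCTTTCTCAAGTT
>synthetic_acceptor_005
TCTTTTCCCTTTATTCTCAGGAC
>synthetic_acceptor_006
CCCACTTCTCTTTTTTCCAAGCA
>synthetic_acceptor_007
TCATTTTTTCTCTGCACTAGTCG
>synthetic_acceptor_008
TTGCCTTGTTTGCTTCCCAGGAG
>synthetic_acceptor_009
TTTCTTGCTTCCTTATTAAGAAG
>synthetic_acceptor_010
CCTTTCTGTGCGGCCTGTAGGGC
>synthetic_acceptor_011
CCTTTTCCCCTCTCTCTCAGGTT
>synthetic_acceptor_012
TCTCTTCTCCTGCCTGTTAGTTG
>synthetic_acceptor_013
CTCTTCTTTTGTTCCCGTAGGAG
>synthetic_acceptor_014
CCTGCTTACCCCTTTCTTAGGAG
>synthetic_acceptor_015
TCCCCTTTTTTTTTTTTTAGGCC
>synthetic_acceptor_016
CCTCCATCTTCTCCTTCTAGACC
>synthetic_acceptor_017
TCGTTCTTTTTTTCCCTTAGATT
>synthetic_acceptor_018
CCTTGCTTTTCCCTCCCCAGGCC
>synthetic_acceptor_019
CCTCCTCTATCTCCTTTTAGCTC
>synthetic_acceptor_020
TTTTTCTTTTTTTCTTTCAGATA
>synthetic_acceptor_021
CCCCTTCTTTTCCTTTCTAGGGG
>synthetic_acceptor_022
CATCTTCCTCTTTCCTTGAGCTG
>synthetic_acceptor_023
TTCTTCTCTTTCTTTTTTAGGTA
>synthetic_acceptor_024
TGTCTCCTCTCCTTCTTTAGCTT
>synthetic_acceptor_025
CCCCTCCTTTTTCTTCTGAGGTG
>synthetic_acceptor_026
TTCTCTCTTTTCTCTCCCAGATG
>synthetic_acceptor_027
TCCCTTCCTTCCCCCTCCAGATT
>synthetic_acceptor_028
TCTTTCCAAAACTTTTCCAGGAA
>synthetic_acceptor_029
TCTTCTTTTCTCCTCTCAAGTCA
>synthetic_acceptor_030
CCCTCTTTTTCTCTCCTTAGCAG
>synthetic_acceptor_031
CTCTTTTCTGTTTTTCTTAGGAG
>synthetic_acceptor_032
TCTCCTTTTGCTGCTCCTAGGCC
>synthetic_acceptor_033
GTGTTTTTGTTTTTTCGTAGCTC
>synthetic_acceptor_034
TATCCTCTTCTCCTCCGTAGAGA
>synthetic_acceptor_035
ACTATCTCCTGTTTTCCTAGGGG
>synthetic_acceptor_036
TCTTTCTCTTTCTCCTGCAGGTC
>synthetic_acceptor_037
ATCATTTTTTTCTTCATCAGACA
>synthetic_acceptor_038
CCCTCCTATTCTTTTTCCAGTCA
>synthetic_acceptor_039
CTTTTCTTCCTCCTCCCCAGGAT
>synthetic_acceptor_040
TTCCTCTTTCTCTCGTTTAGCCG
>synthetic_acceptor_041
TCGTTACTTCCTCTCGGTAGGCC
>synthetic_acceptor_042
TCGTTTTGCCTCCTCCTCAGGCG
>synthetic_acceptor_043
TTCCATCTTCTTTTCCCCAGGCT
>synthetic_acceptor_044
TCTTATCCTCCCCTTTTTAGTTA
>synthetic_acceptor_045
CATCCTCTTCCCTTTCTTAGTGG
>synthetic_acceptor_046
CCTCTCTGTTTTGTTTGTAGAGA
>synthetic_acceptor_047
CTTCTTCCGGTTCTCTGAAGGCA
>synthetic_acceptor_048
GTCGCATTCATTCTTTGTAGGAT
>synthetic_acceptor_049
TCTTTCTACTTCTTTTCCAGGGG
>synthetic_acceptor_050
CTGCTCTTTGTTCCCCTTAGGTT
>synthetic_acceptor_051
TCCCTCTTTCCCTCTCCCAGGAA
>synthetic_acceptor_052
CTATCATCTCTTCCATTCAGGCA
>synthetic_acceptor_053
TCCTTGCCGTTCTGCTTTAGGAT
>synthetic_acceptor_054
CCTTCTTTCTCTACTCTTAGGAA
>synthetic_acceptor_055
CTCTCCGTTTCTCCCTCTAGGAA
>synthetic_acceptor_056
CTTCCCTTTCTGTCTTCTAGCGT
>synthetic_acceptor_057
TCTTCCTTCTCTCCTCTCAGCAC
>synthetic_acceptor_058
CCTCCTTCTTTTTCCCTTAGTGG
>synthetic_acceptor_059
CTTTTTCCCTCACCTTCCAGTAG
>synthetic_acceptor_060
TCGCTTTCCCCCCCCCTTAGGAT
>synthetic_acceptor_061
TCTCTCTTCCTCTTTCTAAGTGA
>synthetic_acceptor_062
CCCTTTTTTTCGCCCCTTAGCGG
>synthetic_acceptor_063
TATTTGCCCTCCTTCGGTAGGAC
>synthetic_acceptor_064
TCTCTTTCCTTCCCTTTCAGAAA
>synthetic_acceptor_065
CCACCTTTTGTCTTCGCTAGGCT
>synthetic_acceptor_066
CCCATTTCCTTTTTTCTTAGGCT
>synthetic_acceptor_067
CGTTCTGGCCCCCTTTCTAGGTT
>synthetic_acceptor_068
TCGCTCCTTTTGCTTCCCAGGCA
>synthetic_acceptor_069
CCTTCCTTCCCATCTCCTAGGCA
>synthetic_acceptor_070
ACTGTCCCTTCTCCCTCTCGGCG
>synthetic_acceptor_071
CGCTTATCCTTCCCCTCTAGACC
>synthetic_acceptor_072
TCTTTCTTCTCGCCCCCCAGTAT
>synthetic_acceptor_073
TCACTTTTTCTATTCCCTAGCGG
>synthetic_acceptor_074
CCTCTTCCCGCCTGCTCCAGCTA
>synthetic_acceptor_075
TTCCTCTCTTCTTCTTCTAGGCT
>synthetic_acceptor_076
TCCCTCCCCTTTTCGGTCAGGTG
>synthetic_acceptor_077
CTCCTTCTTTACCCCACTAGGGG
>synthetic_acceptor_078
TCTGTCTATCTTCTTTCTAGGAC
>synthetic_acceptor_079
TTTTCCTTTCTTCTCTTCAGCGA
>synthetic_acceptor_080
TCCTTTTTCTCTTTCTCTAGCGT
>synthetic_acceptor_081
TAAGCTTCGTGATTTTTCAGACG
>synthetic_acceptor_082
CGCTCCCTTCTTGTCTCCAGAGA
>synthetic_acceptor_083
TTTTCCTTATTCTTTTCTAGGTC
>synthetic_acceptor_084
CCAGCTCTTTCTCTTTTCAGGTG
>synthetic_acceptor_085
TCCGCCTCTCCTCCATTTAGTTG
>synthetic_acceptor_086
TCTTTCATTCTTTCTCTCAGGTC
>synthetic_acceptor_087
TCTCCCTTTCTAGTTCCCAGGTT
>synthetic_acceptor_088
TTCTCAGTTCCCATTTCCAGGCT
>synthetic_acceptor_089
ACCTCCTTTCTTTTTCCTAGGCT
>synthetic_acceptor_090
TTCCCTCCTCCCTCTCTTAGCTT
>synthetic_acceptor_091
CACCTCTCTTTCGTTCTCAGTCG
>synthetic_acceptor_092
TTTACCTTCACTTCTCCTAGGAA
>synthetic_acceptor_093
CCCCCTATTTTTTTCTAAAGCCC
>synthetic_acceptor_094
ATCCCTTTATCTTTACTAAGAAC
>synthetic_acceptor_095
GCTCCTCCTTTTCTCTTTAGGCC
>synthetic_acceptor_096
TTACTCTTCCTTCCTCCTAGATG
>synthetic_acceptor_097
TTCCTCCTTCTATCCCTCAGGCA
>synthetic_acceptor_098
TCTTCTCTTTTTTAACCTAGGGC
>synthetic_acceptor_099
CCCCCCACCCCCTCCTATAGATT
>synthetic_acceptor_100
CTATTCCCCTCTTTCTCTAGGAC
>synthetic_acceptor_101
CTTTGCTTTCTTCCTTCTAGCCT
>synthetic_acceptor_102
CTCTTACCTCCTATCTCTAGATT
>synthetic_acceptor_103
TTCCCTTTCTCTCCTCTTCGGTT
>synthetic_acceptor_104
TTCTGTCCTTTTCTTTTCAGGTT
>synthetic_acceptor_105
TTTTCTCTATCCCAGTCTAGGAC
>synthetic_acceptor_106
TTTTTCGCTTTCTATCTTAGCTG
>synthetic_acceptor_107
ACTTTCATACTCCTTCCCAGGAC
>synthetic_acceptor_108
TATCTTCCATCTTTTTTTAGCAC
>synthetic_acceptor_109
TCATCCCTCCCTCTTCCAAGGAT
>synthetic_acceptor_110
TTTCCTCCCTCTTATTTTAGGTG
>synthetic_acceptor_111
TCCTTCCATTTGACCACCAGCAT
>synthetic_acceptor_112
TCTTCTTTCCCTTTGCCTAGTGG
>synthetic_acceptor_113
CTCGCTTCCTCCTTTCCCAGATG
>synthetic_acceptor_114
CATTCATCCCTGTTCTCTAGGGT
>synthetic_acceptor_115
CTTCTCTTTCTCCTTTGTAGACT
>synthetic_acceptor_116
TCCCCCTCTTTCCCCTCCAGGTT
>synthetic_acceptor_117
TCCTTCTGTCTTTTCTCCAGGCG
>synthetic_acceptor_118
TATTTACTGTCCCTTCTTAGGTG
>synthetic_acceptor_119
CACGTTTATACTTTTTTTAGAGT
>synthetic_acceptor_120
TTGCCTTCCGTCCCTTTTAGGCG
>synthetic_acceptor_121
CCTCTCTTTCATTTCTTTAGCTA
>synthetic_acceptor_122
CTTCTCCCCCCTCCGCGCAGATA
>synthetic_acceptor_123
TTTCTCTCTCACTTTTTTAGGCA
>synthetic_acceptor_124
CTTCTCTTCCCTTCCTTTAGGGC
>synthetic_acceptor_125
TTTCCTTCTTTCCTCCTTAGATC
>synthetic_acceptor_126
CTTTACCTTTCTCTTTGCAGAGG
>synthetic_acceptor_127
CTTTTCCTGTCTCTCCTCAGCCA
>synthetic_acceptor_128
CCTTTTTTCCTCTCCTTTAGATA
>synthetic_acceptor_129
CCTTCTTCTCCCTTTCCTAGGAT
>synthetic_acceptor_130
TTTTCTGCCCTATCTCCTAGATC
>synthetic_acceptor_131
TTGCCTAACTACTCTGTTAGTAC
>synthetic_acceptor_132
TATCTCCTCTCCCCCCAAAGCAT
>synthetic_acceptor_133
CTCATTCACTTTTCTCTAAGGCC
>synthetic_acceptor_134
TTCTATCTCTCCTTTATCAGAAA
>synthetic_acceptor_135
CACCCCCCGTCTTTAGTTAGAGC
>synthetic_acceptor_136
TGTTCCTAGCTTTTACTTAGGCC
>synthetic_acceptor_137
CTACCCCTTGTCCCCTCTAGGCA
>synthetic_acceptor_138
CGCTCTTCCTCCCCCTTTAGGGC
>synthetic_acceptor_139
TTTTTACTTCTGCCTCTCAGACT
>synthetic_acceptor_140
CTTTCCTCCCCTCTCTTGAGTTC
>synthetic_acceptor_141
CTTCTTTCTTCCCGTTTTAGTCT
>synthetic_acceptor_142
TCCTGTTCCTCTCCCTCTAGCGT
>synthetic_acceptor_143
CCTCTTCCTCCGCTTTCTAGAAA
>synthetic_acceptor_144
TTCTTCTCTTATCATCCTAGATC
>synthetic_acceptor_145
CTTTCCTACTCTTTTCCTAGACT
>synthetic_acceptor_146
TGCACTTTTCCTTTCCTCAGAGC
>synthetic_acceptor_147
TCCTTTTTGCTTCGCATTAGCGG
>synthetic_acceptor_148
TCCTTCGCCTCATTTCCTAGGTT
>synthetic_acceptor_149
TTTCCTTTCTACTTTATTAGGGC
>synthetic_acceptor_150
TTCGATTTCTACTTTCCTAGACC
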