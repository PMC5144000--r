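>synthetic_donor_001
CACGTAAGT
>synthetic_donor_002
CAGGTAAGT
>synthetic_donor_003
CAGGTCAGG
>synthetic_donor_004
GGGGTAAGA
>synthetic_donor_005
CAGGTAGGT
>synthetic_donor_006
ACGGTTAGT
>synthetic_donor_007
GATGTATGA
>synthetic_donor_008
AAGGTGACA
>synthetic_donor_009
AGGGTAGCT
>synthetic_donor_010
ATGGTGAGT
>synthetic_donor_011
TCTGTAAGT
>synthetic_donor_012
CAGGTGTGA
>synthetic_donor_013
CTGGTGAGA
>synthetic_donor_014
GATGTAAGC
>synthetic_donor_015
AGGGTATGG
>synthetic_donor_016
CAGGTAAGG
>synthetic_donor_017
GCTGTGAGG
>synthetic_donor_018
CAGGTAAGT
>synthetic_donor_019
GAGGTAAGT
>synthetic_donor_020
TAGGTAAGT
>synthetic_donor_021
GATGTGAGA
>synthetic_donor_022
AACGTGAGC
>synthetic_donor_023
AAAGTTAGT
>synthetic_donor_024
TTGGTGAGT
>synthetic_donor_025
AGGGTCCGT
>synthetic_donor_026
CGGGTGCGA
>synthetic_donor_027
GAGGTAAGC
>synthetic_donor_028
CAGGTATGT
>synthetic_donor_029
AGGGTGAGC
>synthetic_donor_030
CAGGTAAGT
>synthetic_donor_031
CGGGTAAGT
>synthetic_donor_032
AAGGTGAGA
>synthetic_donor_033
AGGGTACGT
>synthetic_donor_034
CAGGTAACA
>synthetic_donor_035
GCGGTGTCT
>synthetic_donor_036
AACGTAGTC
>synthetic_donor_037
AAGGTAGTT
>synthetic_donor_038
CGCGTAGGC
>synthetic_donor_039
CAGGTGAGT
>synthetic_donor_040
CGCGTGTGT
>synthetic_donor_041
CAGGTAAAG
>synthetic_donor_042
GTGGTGGGT
>synthetic_donor_043
AGCGTACGC
>synthetic_donor_044
CAAGTAATG
>synthetic_donor_045
CCGGTAACC
>synthetic_donor_046
GTGGTAAGT
>synthetic_donor_047
TAGGAGGGT
>synthetic_donor_048
AAGGTGAGT
>synthetic_donor_049
GAGGTGAGC
>synthetic_donor_050
CAGGTGTGT
>synthetic_donor_051
CAGGTAAGT
>synthetic_donor_052
AAGGTATGC
>synthetic_donor_053
TTGGTAAGT
>synthetic_donor_054
GCGGTAAGA
>synthetic_donor_055
GAGGTGGGT
>synthetic_donor_056
CTGGTAATA
>synthetic_donor_057
TAGGTCAGT
>synthetic_donor_058
CAGGTTAAC
>synthetic_donor_059
CCGGTATGC
>synthetic_donor_060
CACGCTAGT
>synthetic_donor_061
AAGGTAAGT
>synthetic_donor_062
ATGGTAGGT
>synthetic_donor_063
CTGGTGAGT
>synthetic_donor_064
CAGGTATTT
>synthetic_donor_065
CCGGTAAGC
>synthetic_donor_066
GGTGTAAGC
>synthetic_donor_067
CAAGTATGT
>synthetic_donor_068
TTGGTACGT
>synthetic_donor_069
AACGTAAGC
>synthetic_donor_070
GAGGTAAGT
>synthetic_donor_071
CAGGTGATA
>synthetic_donor_072
AAGGTAAGC
>synthetic_donor_073
AAGGTCAGC
>synthetic_donor_074
CAGGTAGGT
>synthetic_donor_075
GAGGTAAGT
>synthetic_donor_076
AAGGTGAAC
>synthetic_donor_077
AGAGTAAGT
>synthetic_donor_078
GAAGTAAGT
>synthetic_donor_079
CAGGTGAGT
>synthetic_donor_080
CTGGTGAGC
>synthetic_donor_081
AGGGTGAGG
>synthetic_donor_082
ATGGTGAGA
>synthetic_donor_083
AAAGTGGGT
>synthetic_donor_084
TGGGTGCGA
>synthetic_donor_085
CAGGTATGC
>synthetic_donor_086
GTGGTAAGT
>synthetic_donor_087
AAGGTATCT
>synthetic_donor_088
CTAGTAAGT
>synthetic_donor_089
AAGGTGAGA
>synthetic_donor_090
GCGGTTAGT
>synthetic_donor_091
GAGGTGTGA
>synthetic_donor_092
TAGGTGAGG
>synthetic_donor_093
GGAGTGTGA
>synthetic_donor_094
GAAGTAAGT
>synthetic_donor_095
CAGGTAGGT
>synthetic_donor_096
GCGGTAAGG
>synthetic_donor_097
ATGGTACGG
>synthetic_donor_098
GAGGTAAGT
>synthetic_donor_099
AAGGTGAGG
>synthetic_donor_100
AGGGTGAGC
>synthetic_donor_101
CCGGTTCGC
>synthetic_donor_102
CAGGTATGT
>synthetic_donor_103
TCGGTGTGT
>synthetic_donor_104
GAGGTAAAT
>synthetic_donor_105
TAGGTAAGT
>synthetic_donor_106
CCGGTCTGC
>synthetic_donor_107
TAGGTAACG
>synthetic_donor_108
TAGGTAGGT
>synthetic_donor_109
CAGGTGAGC
>synthetic_donor_110
AAGGTGAGG
>synthetic_donor_111
AACGTAAGC
>synthetic_donor_112
AAGGTAGGT
>synthetic_donor_113
CAGGTGCGT
>synthetic_donor_114
CAAGTAATC
>synthetic_donor_115
CGGGTTAGG
>synthetic_donor_116
TGGGTAAGT
>synthetic_donor_117
TCGGTGTGT
>synthetic_donor_118
ACGGTGAGT
>synthetic_donor_119
GGGGTGAGT
>synthetic_donor_120
GAGGTAGGT
>synthetic_donor_121
GGGGTAAGT
>synthetic_donor_122
CGGGTAAGG
>synthetic_donor_123
GAGGTGAGA
>synthetic_donor_124
GGAGTAAGA
>synthetic_donor_125
TGGGTGAGC
>synthetic_donor_126
GAGGTAAGA
>synthetic_donor_127
TAAGTAAGT
>synthetic_donor_128
AAGGTAAGT
>synthetic_donor_129
CAGGTATGA
>synthetic_donor_130
CGGGTAAGG
>synthetic_donor_131
AAGGTAAGT
>synthetic_donor_132
AATGTGAGC
>synthetic_donor_133
CAGGTAAAT
>synthetic_donor_134
GTGGTATGA
>synthetic_donor_135
CGGGTAAGT
>synthetic_donor_136
CAGGTAAGA
>synthetic_donor_137
CCCGTGAAG
>synthetic_donor_138
CAAGTAAGA
>synthetic_donor_139
GAGGTAGGC
>synthetic_donor_140
ATGGTGAGT
>synthetic_donor_141
AGGGTGTAA
>synthetic_donor_142
CAGGTGTGC
>synthetic_donor_143
CAGGTAAGT
>synthetic_donor_144
AGGGTAAGG
>synthetic_donor_145
CAGGTAAGT
>synthetic_donor_146
CGGGTACGC
>synthetic_donor_147
GAGGTGTGA
>synthetic_donor_148
CGGGTAAGT
>synthetic_donor_149
AGGGTAAGT
>synthetic_donor_150
TGGGTATGT
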