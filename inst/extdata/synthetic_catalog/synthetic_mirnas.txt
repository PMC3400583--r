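# synthetic stand-in mature miRNA identifiers (generated, not curated)
hsa-miR-s0001
hsa-miR-s0002
hsa-miR-s0003
hsa-miR-s0004
hsa-miR-s0005
hsa-miR-s0006
hsa-miR-s0007
hsa-miR-s0008
hsa-miR-s0009
hsa-miR-s0010
hsa-miR-s0011
hsa-miR-s0012
hsa-miR-s0013
hsa-miR-s0014
hsa-miR-s0015
hsa-miR-s0016
hsa-miR-s0017
hsa-miR-s0018
hsa-miR-s0019
hsa-miR-s0020
hsa-miR-s0021
hsa-miR-s0022
hsa-miR-s0023
hsa-miR-s0024
hsa-miR-s0025
hsa-miR-s0026
hsa-miR-s0027
hsa-miR-s0028
hsa-miR-s0029
hsa-miR-s0030
hsa-miR-s0031
hsa-miR-s0032
hsa-miR-s0033
hsa-miR-s0034
hsa-miR-s0035
hsa-miR-s0036
hsa-miR-s0037
hsa-miR-s0038
hsa-miR-s0039
hsa-miR-s0040
hsa-miR-s0041
hsa-miR-s0042
hsa-miR-s0043
hsa-miR-s0044
hsa-miR-s0045
hsa-miR-s0046
hsa-miR-s0047
hsa-miR-s0048
hsa-miR-s0049
hsa-miR-s0050
hsa-miR-s0051
hsa-miR-s0052
hsa-miR-s0053
hsa-miR-s0054
hsa-miR-s0055
hsa-miR-s0056
hsa-miR-s0057
hsa-miR-s0058
hsa-miR-s0059
hsa-miR-s0060
hsa-miR-s0061
hsa-miR-s0062
hsa-miR-s0063
hsa-miR-s0064
hsa-miR-s0065
hsa-miR-s0066
hsa-miR-s0067
hsa-miR-s0068
hsa-miR-s0069
hsa-miR-s0070
hsa-miR-s0071
hsa-miR-s0072
hsa-miR-s0073
hsa-miR-s0074
hsa-miR-s0075
hsa-miR-s0076
hsa-miR-s0077
hsa-miR-s0078
hsa-miR-s0079
hsa-miR-s0080
hsa-miR-s0081
hsa-miR-s0082
hsa-miR-s0083
hsa-miR-s0084
hsa-miR-s0085
hsa-miR-s0086
hsa-miR-s0087
hsa-miR-s0088
hsa-miR-s0089
hsa-miR-s0090
hsa-miR-s0091
hsa-miR-s0092
hsa-miR-s0093
hsa-miR-s0094
hsa-miR-s0095
hsa-miR-s0096
hsa-miR-s0097
hsa-miR-s0098
hsa-miR-s0099
hsa-miR-s0100
hsa-miR-s0101
hsa-miR-s0102
hsa-miR-s0103
hsa-miR-s0104
hsa-miR-s0105
hsa-miR-s0106
hsa-miR-s0107
hsa-miR-s0108
hsa-miR-s0109
hsa-miR-s0110
hsa-miR-s0111
hsa-miR-s0112
hsa-miR-s0113
hsa-miR-s0114
hsa-miR-s0115
hsa-miR-s0116
hsa-miR-s0117
hsa-miR-s0118
hsa-miR-s0119
hsa-miR-s0120
hsa-miR-s0121
hsa-miR-s0122
hsa-miR-s0123
hsa-miR-s0124
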