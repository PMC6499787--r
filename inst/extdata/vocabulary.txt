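CE1
CE10
CE11
CE12
CE15
CE2
CE3
CE4
CE6
CE7
CE8
CE9
GH1
GH10
GH105
GH106
GH107
GH108
GH109
GH110
GH115
GH117
GH123
GH13_14
GH13_36
GH13_38
GH13_39
GH13_8
GH13_9
GH130
GH144
GH146
GH147
GH148
GH149
GH150
GH151
GH16
GH18
GH2
GH20
GH23
GH24
GH25
GH26
GH27
GH28
GH29
GH3
GH30_1
GH30_2
GH30_3
GH30_4
GH31
GH32
GH33
GH35
GH36
GH38
GH39
GH4
GH42
GH43_1
GH43_10
GH43_12
GH43_2
GH43_24
GH43_29
GH43_4
GH43_8
GH5_13
GH5_2
GH5_4
GH5_46
GH5_7
GH51
GH53
GH55
GH63
GH73
GH76
GH77
GH78
GH88
GH89
GH9
GH92
GH95
GH97
GH99
Pept
PL1
PL11
PL12
PL13
PL17
PL27
PL28
PL29
PL33
PL38
PL40
PL6
PL7
PL8
PL9
Sulf
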