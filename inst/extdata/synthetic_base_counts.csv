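count
273
717
1101
1969
23
56
82
525
1480
3700
378
1140
1207
66
34
75
579
1441
1538
954
74
227
1011
26
89
1827
55
851
2145
25
53
39
1006
1397
39
13
82
1597
133
1039
47
1811
40
1218
698
73
672
57
772
1975
702
74
509
1553
1121
30
24
709
1730
665
1129
30
1379
71
99
495
1304
65
36
59
36
19
1095
1106
40
63
916
147
303
1327
1122
957
73
82
882
5778
613
2717
105
2725
2049
94
176
14
75
2199
1488
121
82
2262
46
2148
128
134
789
86
811
49
41
2487
107
1808
587
39
1253
65
117
47
68
1293
45
1252
722
68
56
1070
1861
967
1011
57
946
956
69
134
129
639
520
77
50
46
34
1441
57
1784
61
791
650
175
50
60
2153
109
29
1653
71
193
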