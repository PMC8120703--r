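age,qx
65,0.02118562702
66,0.02328477151
67,0.02559944848
68,0.02815118152
69,0.03096350983
70,0.03406214708
71,0.0374751459
72,0.04123306622
73,0.0453691453
74,0.04991946639
75,0.05492312208
76,0.06042236752
77,0.066462757
78,0.07309325646
79,0.08036632206
80,0.08833793352
81,0.09706756816
82,0.1066180992
83,0.1170555988
84,0.1284490238
85,0.1408697573
86,0.1543909788
87,0.1690868284
88,0.1850313331
89,0.2022970557
90,0.2209534323
91,0.2410647604
92,0.2626878098
93,0.2858690309
94,0.3106413549
95,0.3370205948
96,0.3650014876
97,0.3945534516
98,0.4256161829
99,0.4580952667
100,1
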