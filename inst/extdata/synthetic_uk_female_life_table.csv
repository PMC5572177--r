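age,qx
60,0.005192
61,0.005765
62,0.006401
63,0.007107
64,0.007891
65,0.008761
66,0.009726
67,0.010797
68,0.011985
69,0.013303
70,0.014765
71,0.016386
72,0.018184
73,0.020177
74,0.022385
75,0.024833
76,0.027544
77,0.030546
78,0.03387
79,0.037548
80,0.041618
81,0.046117
82,0.05109
83,0.056584
84,0.062648
85,0.069338
86,0.076712
87,0.084835
88,0.093773
89,0.103598
90,0.114386
91,0.126217
92,0.139172
93,0.153336
94,0.168795
95,0.185636
96,0.203941
97,0.22379
98,0.245258
99,0.268407
100,0.293287
101,0.319932
102,0.34835
103,0.378525
104,0.410406
105,0.443902
106,0.478881
107,0.51516
108,0.552502
109,0.590617
110,1
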