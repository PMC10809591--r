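age,qx
0,0.003992
1,0.000538
2,0.000542
3,0.000546
4,0.000551
5,0.000556
6,0.000561
7,0.000567
8,0.000574
9,0.000581
10,0.000589
11,0.000598
12,0.000608
13,0.000619
14,0.00063
15,0.000643
16,0.000657
17,0.000673
18,0.00069
19,0.000709
20,0.000729
21,0.000752
22,0.000777
23,0.000804
24,0.000834
25,0.000867
26,0.000903
27,0.000942
28,0.000986
29,0.001034
30,0.001087
31,0.001144
32,0.001208
33,0.001278
34,0.001354
35,0.001438
36,0.001531
37,0.001632
38,0.001744
39,0.001867
40,0.002001
41,0.002149
42,0.002311
43,0.00249
44,0.002686
45,0.002901
46,0.003137
47,0.003397
48,0.003682
49,0.003995
50,0.004339
51,0.004716
52,0.005131
53,0.005586
54,0.006086
55,0.006635
56,0.007238
57,0.007899
58,0.008625
59,0.009423
60,0.010298
61,0.011258
62,0.012312
63,0.013469
64,0.014738
65,0.01613
66,0.017658
67,0.019333
68,0.021169
69,0.023183
70,0.025391
71,0.02781
72,0.030461
73,0.033365
74,0.036545
75,0.040027
76,0.043837
77,0.048005
78,0.052563
79,0.057546
80,0.062989
81,0.068932
82,0.075418
83,0.08249
84,0.090198
85,0.09859
86,0.107721
87,0.117645
88,0.128419
89,0.140104
90,0.152761
91,0.16645
92,0.181233
93,0.197171
94,0.214323
95,0.232744
96,0.252482
97,0.273581
98,0.296074
99,0.319981
100,0.34531
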