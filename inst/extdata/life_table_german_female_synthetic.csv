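age,q_all
20,0.00015956583
21,0.00016659352
22,0.0001744336
23,0.00018318
24,0.00019293746
25,0.00020382286
26,0.00021596656
27,0.000229514
28,0.00024462742
29,0.00026148781
30,0.00028029708
31,0.00030128043
32,0.00032468913
33,0.00035080341
34,0.00037993593
35,0.00041243541
36,0.00044869087
37,0.0004891362
38,0.00053425544
39,0.00058458843
40,0.00064073736
41,0.00070337386
42,0.00077324703
43,0.00085119238
44,0.00093814169
45,0.0010351342
46,0.0011433287
47,0.0012640175
48,0.0013986419
49,0.0015488085
50,0.001716309
51,0.0019031409
52,0.0021115308
53,0.0023439611
54,0.0026031984
55,0.0028923262
56,0.0032147807
57,0.0035743907
58,0.0039754216
59,0.0044226245
60,0.004921291
61,0.0054773128
62,0.0060972488
63,0.0067883987
64,0.0075588843
65,0.0084177391
66,0.0093750079
67,0.010441854
68,0.011630682
69,0.012955262
70,0.014430881
71,0.01607449
72,0.017904881
73,0.019942861
74,0.02221146
75,0.024736131
76,0.027544984
77,0.030669019
78,0.034142376
79,0.038002598
80,0.04229089
81,0.047052391
82,0.05233643
83,0.058196781
84,0.064691881
85,0.071885024
86,0.079844491
87,0.088643614
88,0.098360731
89,0.10907901
90,0.12088613
91,0.13387369
92,0.14813642
93,0.16377105
94,0.18087479
95,0.19954337
96,0.21986854
97,0.24193502
98,0.26581681
99,0.29157277
100,0.31924152
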