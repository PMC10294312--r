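age,q_cancer
20,3.1913166e-06
21,4.6646185e-06
22,6.2796097e-06
23,8.0599199e-06
24,1.0032748e-05
25,1.2229371e-05
26,1.4685726e-05
27,1.7443064e-05
28,2.0548703e-05
29,2.4056879e-05
30,2.8029708e-05
31,3.3743409e-05
32,4.0261452e-05
33,4.7709264e-05
34,5.6230518e-05
35,6.5989666e-05
36,7.7174829e-05
37,9.0001061e-05
38,0.00010471407
39,0.00012159439
40,0.00014096222
41,0.000156149
42,0.00017320734
43,0.00019236948
44,0.00021389631
45,0.00023808086
46,0.00026525225
47,0.00029578011
48,0.00033007948
49,0.00036861643
50,0.00041191417
51,0.00044914125
52,0.00048987516
53,0.00053442313
54,0.00058311644
55,0.00063631176
56,0.00068153352
57,0.00072917571
58,0.00077918263
59,0.00083145341
60,0.00088583238
61,0.0009420978
62,0.00099994881
63,0.0010589902
64,0.0011187149
65,0.0011784835
66,0.001237501
67,0.00129479
68,0.0013491591
69,0.0013991683
70,0.0014430881
71,0.0015270766
72,0.0016114393
73,0.0016951432
74,0.0017769168
75,0.0018552098
76,0.0019281489
77,0.0019934862
78,0.0020485426
79,0.0020901429
80,0.0021145445
81,0.0022114624
82,0.0023028029
83,0.002386068
84,0.0024582915
85,0.0025159758
86,0.0025550237
87,0.0025706648
88,0.002557379
89,0.0025088173
90,0.0024177226
91,0.0025436
92,0.0026664555
93,0.0027841079
94,0.0028939967
95,0.0029931505
96,0.0030781595
97,0.0031451553
98,0.0031898018
99,0.0032073005
100,0.0031924152
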