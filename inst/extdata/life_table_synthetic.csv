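age,qx
18,0.0007
20,0.0009
25,0.0010
30,0.0010
35,0.0012
40,0.0017
45,0.0027
50,0.0041
55,0.0060
60,0.0089
65,0.0133
70,0.0203
75,0.0313
80,0.0502
85,0.0823
90,0.1358
95,0.2062
100,0.3000
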