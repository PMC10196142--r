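generation,mean_length_cm,mean_diameter_cm,cv_length,cv_diameter
0,12.0,1.80,0.3,0.3
1,4.76,1.22,0.3,0.3
2,1.90,0.83,0.3,0.3
3,0.76,0.56,0.3,0.3
4,1.27,0.45,0.3,0.3
5,1.07,0.35,0.3,0.3
6,0.90,0.28,0.3,0.3
7,0.76,0.23,0.3,0.3
8,0.64,0.186,0.3,0.3
9,0.54,0.154,0.3,0.3
10,0.46,0.130,0.3,0.3
11,0.39,0.109,0.3,0.3
12,0.33,0.095,0.3,0.3
13,0.27,0.082,0.3,0.3
14,0.23,0.074,0.3,0.3
15,0.20,0.066,0.3,0.3
16,0.165,0.060,0.3,0.3
17,0.141,0.054,0.3,0.3
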