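case,kidneys_olinda,kidneys_voxelmed,liver_olinda,liver_voxelmed,spleen_olinda,spleen_voxelmed
1,0.84,0.99,0.13,0.11,1.34,1.26
2,0.69,0.83,0.08,0.09,0.57,0.70
3,0.42,0.52,0.15,0.16,0.28,0.30
4,0.44,0.46,NA,NA,0.21,0.25
5,0.56,0.67,0.38,0.42,0.06,0.07
6,0.33,0.39,1.11,1.47,0.24,0.27
7,0.57,0.59,0.13,0.12,0.88,0.80
8,0.42,0.52,0.05,0.05,0.20,0.22
9,0.79,0.79,0.06,0.07,0.48,0.52
10,1.30,1.63,0.23,0.27,0.91,1.14
11,0.76,0.91,0.40,0.33,0.59,0.96
12,0.55,0.80,0.15,0.16,0.27,0.30
13,0.43,0.49,0.04,0.04,0.15,0.14
14,0.33,0.40,0.08,0.09,NA,NA
15,0.66,0.75,0.17,0.18,1.08,1.18
16,0.27,0.31,0.03,0.03,0.17,0.18
17,1.89,2.26,0.45,0.51,1.26,1.44
18,0.78,0.90,0.18,0.21,0.98,1.12
19,0.90,1.03,0.15,0.17,1.09,1.13
20,0.68,0.80,0.08,0.09,0.76,0.89
21,0.47,0.55,0.20,0.22,0.41,0.45
22,0.55,0.66,0.24,0.26,0.73,0.85
23,0.57,0.53,0.22,0.25,1.14,1.33
24,0.53,0.61,0.11,0.12,0.45,0.50
25,1.04,1.01,0.14,0.15,0.65,0.72
26,0.54,0.65,0.11,0.11,0.54,0.59
27,0.27,0.31,0.08,0.09,NA,NA
28,0.37,0.43,0.11,0.13,0.57,0.65
29,0.50,0.49,0.06,0.07,0.50,0.48
30,1.00,1.08,0.10,0.10,0.67,0.68
31,0.38,0.40,0.22,0.22,0.16,0.17
32,0.34,0.40,1.00,1.13,0.44,0.54
33,0.31,0.35,0.12,0.12,0.22,0.24
34,0.48,0.39,0.13,0.13,0.28,0.23
35,0.26,0.30,0.02,0.02,0.08,0.09
36,0.64,0.75,0.11,0.12,0.73,0.84
37,0.62,0.71,0.34,0.37,1.76,1.94
38,0.50,0.56,0.11,0.12,0.55,0.62
39,0.85,0.99,0.14,0.16,1.24,1.40
40,0.59,0.67,0.06,0.07,0.51,0.56
41,0.29,0.33,0.79,0.91,0.24,0.26
42,0.52,0.60,0.13,0.14,0.43,0.47
43,0.27,0.30,0.03,0.03,0.12,0.13
44,0.18,0.20,0.23,0.25,0.45,0.50
45,0.86,1.09,0.05,0.06,0.35,0.41
46,0.50,0.58,0.08,0.09,0.29,0.33
47,0.40,0.45,0.05,0.06,0.70,0.76
48,0.69,0.78,0.11,0.12,1.11,1.24
49,0.60,0.55,0.07,0.08,1.45,1.34
50,0.65,0.76,0.03,0.02,0.23,0.26
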