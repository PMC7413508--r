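case,kidneys_olinda,kidneys_voxelmed,kidneys_voxelmed_lrd,kidneys_raydose,liver_olinda,liver_voxelmed,liver_voxelmed_lrd,liver_raydose,spleen_olinda,spleen_voxelmed,spleen_voxelmed_lrd,spleen_raydose
1,0.62,0.54,0.54,0.54,0.04,0.03,0.03,0.03,1.11,1.05,1.08,1.04
2,0.40,0.36,0.37,0.40,0.23,0.20,0.22,0.22,0.16,0.16,0.16,0.20
3,0.87,0.76,0.77,0.78,0.40,0.37,0.38,0.38,0.58,0.47,0.49,0.49
4,0.32,0.28,0.29,0.29,0.12,0.11,0.12,0.12,0.22,0.19,0.20,0.19
5,0.42,0.36,0.36,0.37,0.04,0.03,0.04,0.04,0.12,0.10,0.12,0.11
6,0.52,0.44,0.46,0.46,0.11,0.10,0.11,0.11,0.92,0.83,0.87,0.84
7,0.39,0.33,0.34,0.34,0.10,0.08,0.08,0.09,0.46,0.39,0.44,0.43
8,0.75,0.66,0.66,0.67,0.02,0.03,0.03,0.03,0.28,0.24,0.27,0.26
9,0.36,0.30,0.30,0.34,1.65,1.45,1.56,1.55,0.38,0.31,0.33,0.36
10,0.62,0.55,0.56,0.54,0.08,0.07,0.07,0.08,NA,NA,NA,NA
11,0.48,0.42,0.45,0.44,0.34,0.30,0.35,0.33,0.67,0.58,0.90,0.84
12,0.66,0.57,0.56,0.57,0.13,0.10,0.11,0.12,0.21,0.17,0.18,0.19
13,0.30,0.25,0.26,0.28,0.08,0.07,0.07,0.08,0.34,0.28,0.33,0.34
14,0.48,0.42,0.42,0.41,0.06,0.05,0.06,0.06,0.10,0.08,0.09,0.09
15,0.40,0.34,0.36,0.36,0.03,0.03,0.03,0.04,0.62,0.54,0.68,0.66
16,0.27,0.23,0.25,0.27,0.30,0.27,0.30,0.29,0.52,0.41,0.45,0.45
17,0.29,0.25,0.24,0.24,0.09,0.07,0.07,0.07,0.36,0.29,0.28,0.27
18,0.51,0.45,0.43,0.44,0.07,0.06,0.07,0.07,0.31,0.24,0.24,0.23
19,0.45,0.38,0.40,0.44,1.43,1.20,1.21,1.20,0.83,0.69,0.93,0.95
20,0.38,0.47,0.48,0.51,0.11,0.09,0.10,0.11,0.38,0.30,0.33,0.35
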