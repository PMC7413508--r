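quantity,reported,tolerance
ccc_sample_a_liver,0.97,0.03
ccc_sample_a_spleen,0.85,0.03
ccc_sample_a_kidneys,0.55,0.03
ccc_sample_b_voxelmed_raydose_kidneys,0.98,0.03
ccc_sample_b_voxelmed_raydose_liver,0.99,0.03
ccc_sample_b_voxelmed_raydose_spleen,0.94,0.03
ccc_sample_b_voxelmed_lrd_raydose_kidneys,0.99,0.03
ccc_sample_b_voxelmed_lrd_raydose_liver,1.00,0.03
ccc_sample_b_voxelmed_lrd_raydose_spleen,1.00,0.03
pooled_pct_diff_sample_b_voxelmed_vs_olinda,-13,1.5
pooled_pct_diff_sample_b_voxelmed_vs_raydose,-8,1.5
toroid_min_pct_diff_vs_olinda,-52,1
toroid_max_pct_diff_vs_olinda,-41,1
toroid_min_pct_diff_vs_raydose,-25,1
toroid_max_pct_diff_vs_raydose,-16,1
anthro_mean_pct_diff_vs_olinda,-11,1.5
anthro_mean_pct_diff_vs_raydose,-4,1.5
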