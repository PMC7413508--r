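"file","md5"
"sample_a_doses.csv","e45b4e1a5e66b96c1f9dec867ad54454"
"sample_b_doses.csv","e8a7f8e07c985087243ed348cbcbd5c7"
"phantom_doses.csv","7bc97fef9df5843ce4de0fd23840ae5d"
"reported_statistics.csv","a4c5ee26747a3c3924a6c163cce63dc6"
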