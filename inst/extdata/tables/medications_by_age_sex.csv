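band,panel,sex,n
65-69,TARGET_ONLY,M,2862
65-69,TARGET_ONLY,F,3272
65-69,TARGET_PLUS_FLAG,M,4427
65-69,TARGET_PLUS_FLAG,F,5255
70-74,TARGET_ONLY,M,2528
70-74,TARGET_ONLY,F,2607
70-74,TARGET_PLUS_FLAG,M,4999
70-74,TARGET_PLUS_FLAG,F,6035
75-79,TARGET_ONLY,M,1707
75-79,TARGET_ONLY,F,1980
75-79,TARGET_PLUS_FLAG,M,4091
75-79,TARGET_PLUS_FLAG,F,5535
80-84,TARGET_ONLY,M,854
80-84,TARGET_ONLY,F,1175
80-84,TARGET_PLUS_FLAG,M,2159
80-84,TARGET_PLUS_FLAG,F,3648
85-99,TARGET_ONLY,M,491
85-99,TARGET_ONLY,F,897
85-99,TARGET_PLUS_FLAG,M,1327
85-99,TARGET_PLUS_FLAG,F,3119
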