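band,sex,n
65-69,M,553
65-69,F,589
70-74,M,557
70-74,F,702
75-79,M,465
75-79,F,765
80-84,M,294
80-84,F,542
85-99,M,217
85-99,F,637
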