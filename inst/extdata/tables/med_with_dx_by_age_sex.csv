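band,category,sex,n
65-69,CVD,M,356
65-69,CVD,F,203
70-74,CVD,M,488
70-74,CVD,F,303
75-79,CVD,M,445
75-79,CVD,F,379
80-84,CVD,M,327
80-84,CVD,F,327
85-99,CVD,M,244
85-99,CVD,F,450
65-69,CVA,M,49
65-69,CVA,F,32
70-74,CVA,M,77
70-74,CVA,F,47
75-79,CVA,M,84
75-79,CVA,F,83
80-84,CVA,M,78
80-84,CVA,F,85
85-99,CVA,M,44
85-99,CVA,F,87
65-69,RENAL,M,32
65-69,RENAL,F,27
70-74,RENAL,M,62
70-74,RENAL,F,29
75-79,RENAL,M,76
75-79,RENAL,F,45
80-84,RENAL,M,66
80-84,RENAL,F,54
85-99,RENAL,M,71
85-99,RENAL,F,89
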