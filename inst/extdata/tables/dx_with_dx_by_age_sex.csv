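band,category,sex,n
65-69,CVD,M,42
65-69,CVD,F,34
70-74,CVD,M,78
70-74,CVD,F,70
75-79,CVD,M,79
75-79,CVD,F,123
80-84,CVD,M,77
80-84,CVD,F,154
85-99,CVD,M,91
85-99,CVD,F,218
65-69,CVA,M,6
65-69,CVA,F,6
70-74,CVA,M,20
70-74,CVA,F,11
75-79,CVA,M,22
75-79,CVA,F,36
80-84,CVA,M,29
80-84,CVA,F,37
85-99,CVA,M,11
85-99,CVA,F,49
65-69,RENAL,M,6
65-69,RENAL,F,14
70-74,RENAL,M,18
70-74,RENAL,F,10
75-79,RENAL,M,30
75-79,RENAL,F,27
80-84,RENAL,M,33
80-84,RENAL,F,40
85-99,RENAL,M,28
85-99,RENAL,F,57
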