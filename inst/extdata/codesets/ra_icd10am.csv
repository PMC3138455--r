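code,label
M05,Seropositive rheumatoid arthritis (illustrative placeholder)
M06,Other rheumatoid arthritis (illustrative placeholder)
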