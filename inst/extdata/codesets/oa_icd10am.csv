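code,label
M15,Polyosteoarthritis (illustrative placeholder)
M16,Osteoarthritis of hip (illustrative placeholder)
M17,Osteoarthritis of knee (illustrative placeholder)
M18,Osteoarthritis of first carpometacarpal joint (illustrative placeholder)
M19,Other osteoarthritis (illustrative placeholder)
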