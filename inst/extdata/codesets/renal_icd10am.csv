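code,label
N17,Acute renal failure (illustrative placeholder)
N18,Chronic kidney disease (illustrative placeholder)
N19,Unspecified renal failure (illustrative placeholder)
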