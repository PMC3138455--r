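code,label
584,Acute renal failure (illustrative placeholder)
585,Chronic renal failure (illustrative placeholder)
586,Renal failure unspecified (illustrative placeholder)
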