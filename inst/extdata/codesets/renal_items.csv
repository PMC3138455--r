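code,label
20401,renal therapy A (synthetic item code)
20402,renal therapy B (synthetic item code)
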