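class,n
TARGET_ONLY,18373
TARGET_PLUS_FLAG,40595
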