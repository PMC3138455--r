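code,label
10101,arthritis NSAID A (synthetic item code)
10102,arthritis NSAID B (synthetic item code)
10103,arthritis DMARD A (synthetic item code)
10104,arthritis analgesic A (synthetic item code)
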