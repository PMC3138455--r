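code,label
20301,antiplatelet A (synthetic item code)
20302,antiplatelet B (synthetic item code)
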