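type,n
TARGET,5321
OTHER,28948
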