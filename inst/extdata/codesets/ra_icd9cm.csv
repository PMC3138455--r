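code,label
714,Rheumatoid arthritis and other inflammatory polyarthropathies (illustrative placeholder)
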