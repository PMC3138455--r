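code,label
401,Essential hypertension (illustrative placeholder)
410,Acute myocardial infarction (illustrative placeholder)
411,Other acute ischaemic heart disease (illustrative placeholder)
413,Angina pectoris (illustrative placeholder)
414,Other chronic ischaemic heart disease (illustrative placeholder)
428,Heart failure (illustrative placeholder)
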