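code,label
G45,Transient cerebral ischaemic attacks (illustrative placeholder)
I60,Subarachnoid haemorrhage (illustrative placeholder)
I61,Intracerebral haemorrhage (illustrative placeholder)
I63,Cerebral infarction (illustrative placeholder)
I64,Stroke not specified (illustrative placeholder)
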