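code,label
430,Subarachnoid haemorrhage (illustrative placeholder)
431,Intracerebral haemorrhage (illustrative placeholder)
434,Occlusion of cerebral arteries (illustrative placeholder)
435,Transient cerebral ischaemia (illustrative placeholder)
436,Acute ill-defined cerebrovascular disease (illustrative placeholder)
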