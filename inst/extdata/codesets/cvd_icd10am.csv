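code,label
I10,Essential hypertension (illustrative placeholder)
I11,Hypertensive heart disease (illustrative placeholder)
I20,Angina pectoris (illustrative placeholder)
I21,Acute myocardial infarction (illustrative placeholder)
I25,Chronic ischaemic heart disease (illustrative placeholder)
I50,Heart failure (illustrative placeholder)
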