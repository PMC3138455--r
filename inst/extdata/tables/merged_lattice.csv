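class,n
MEDS_ONLY,26870
DX_ONLY,2171
MEDS_AND_TARGET_DX,3150
MEDS_AND_NONTARGET_DX,28948
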