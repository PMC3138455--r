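code,label
20201,antihypertensive A (synthetic item code)
20202,antihypertensive B (synthetic item code)
20203,beta blocker A (synthetic item code)
20204,statin A (synthetic item code)
20205,anticoagulant A (synthetic item code)
20206,diuretic A (synthetic item code)
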