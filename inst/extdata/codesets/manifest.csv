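file,category,system
oa_icd10am.csv,OA,ICD10AM
oa_icd9cm.csv,OA,ICD9CM
ra_icd10am.csv,RA,ICD10AM
ra_icd9cm.csv,RA,ICD9CM
cvd_icd10am.csv,CVD,ICD10AM
cvd_icd9cm.csv,CVD,ICD9CM
cva_icd10am.csv,CVA,ICD10AM
cva_icd9cm.csv,CVA,ICD9CM
renal_icd10am.csv,RENAL,ICD10AM
renal_icd9cm.csv,RENAL,ICD9CM
oa_ra_items.csv,OA,DRUG_ITEM
cvd_items.csv,CVD,DRUG_ITEM
cva_items.csv,CVA,DRUG_ITEM
renal_items.csv,RENAL,DRUG_ITEM
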