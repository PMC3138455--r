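# Example run configuration: the bundled rofecoxib year-2000 arthritis
# case study at synthetic scale. Code-set files are illustrative
# placeholders shipped with the package.
drug: rofecoxib
indication: OA
index_year: 2000
min_age: 65
lookback_years: 1
high_use_threshold: 3000
target_categories: [OA, RA]
flag_categories: [CVD, CVA, RENAL]
target_systems: [musculoskeletal, gastrointestinal]
flag_threshold: 10
criteria_file: rofecoxib_criteria.csv
eras:
  ICD9CM: {end: 1999-06-30}
  ICD10AM: {start: 1999-07-01}
codesets:
  - {file: codesets/oa_icd10am.csv, category: OA, system: ICD10AM}
  - {file: codesets/oa_icd9cm.csv, category: OA, system: ICD9CM}
  - {file: codesets/ra_icd10am.csv, category: RA, system: ICD10AM}
  - {file: codesets/ra_icd9cm.csv, category: RA, system: ICD9CM}
  - {file: codesets/cvd_icd10am.csv, category: CVD, system: ICD10AM}
  - {file: codesets/cvd_icd9cm.csv, category: CVD, system: ICD9CM}
  - {file: codesets/cva_icd10am.csv, category: CVA, system: ICD10AM}
  - {file: codesets/cva_icd9cm.csv, category: CVA, system: ICD9CM}
  - {file: codesets/renal_icd10am.csv, category: RENAL, system: ICD10AM}
  - {file: codesets/renal_icd9cm.csv, category: RENAL, system: ICD9CM}
  - {file: codesets/oa_ra_items.csv, category: OA, system: DRUG_ITEM}
  - {file: codesets/cvd_items.csv, category: CVD, system: DRUG_ITEM}
  - {file: codesets/cva_items.csv, category: CVA, system: DRUG_ITEM}
  - {file: codesets/renal_items.csv, category: RENAL, system: DRUG_ITEM}
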