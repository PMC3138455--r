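# adewatch

Forecast adverse-drug-event (ADE) risk for newly released drugs by
confronting what the pre-release clinical trials *excluded* with what the
real-world target population actually *carries*.

When a new drug is listed for subsidy, uptake is fastest among older
patients — exactly the group that randomised controlled trials tend to
exclude for comorbidities (cardiovascular, cerebrovascular, renal disease)
and co-medications. Once a patient group is excluded from every trial,
there is effectively *no evidence* on the drug's action in that group, and
post-release harm tends to surface there first. `adewatch` implements a
three-part risk-identification pipeline for pharmacoepidemiologists and
medicines-safety analysts working with person-linked administrative health
data:

1. **Trial exclusion profile** — the exclusion protocols of the drug's
   trials, curated into a structured criteria file, are aggregated per
   indication into a set of excluded `(domain, category)` factors
   (`parse_criteria_file()`, `aggregate_exclusions()`). Exclusions that
   merely enable the trial's own research question (e.g. gastric
   morbidity in a gastric-safety trial) are separated from
   *other-body-system* exclusions, which are the risk carriers
   (`classify_relevance()`).
2. **Real-world cohort profile** — person-linked pharmaceutical
   dispensing claims and hospital separation records are read, validated
   and classified (`read_dispensing()`, `read_morbidity()`,
   `build_profiles()`). A person enters the index-year cohort when old
   enough (default 65+) and carrying target-morbidity evidence: a
   target-category dispensing, or a target diagnosis code in the primary
   *or any secondary* field of a hospital record. Diagnosis matching is
   dot-aware ICD prefix matching across both coding eras (ICD-9-CM /
   ICD-10-AM), with era-inconsistent records flagged, never remapped.
   Members are classified on the medication dichotomy
   (`classify_patient()`: target drugs only vs target plus flag drugs)
   and on the four-class merged medication/morbidity lattice
   (`merge_profiles()`), then cross-tabulated by age band and sex
   (`cross_tab()`, `prevalence()`, `sex_ratio()`).
3. **Discordance advisory** — the two profiles are compared
   (`compare_profiles()`): every other-system excluded factor is scored
   with its real-world carrier count and prevalence (medication evidence
   over the target-medication cohort, diagnosis evidence over the merged
   cohort), factors above a prevalence threshold (default 10%) are
   flagged, and a deterministic prescriber advisory is rendered
   (`render_advisory()`).

For a medication dichotomy with counts $n_{\text{only}}$ and
$n_{\text{plus}}$, the headline statistic is the co-medication prevalence
$100\,n_{\text{plus}} / (n_{\text{only}} + n_{\text{plus}})$, reported
with half-up rounding; male:female ratios are
$\big(\mathrm{round}(100\,M/(M+F)),\ 100 - \mathrm{round}(100\,M/(M+F))\big)$.

Because linkage-unit extracts are not redistributable, the package also
ships a seeded synthetic generator (`population_spec()`,
`generate_population()`, `calibrate_to_marginals()`) that emulates the
linked-record structure — age/sex composition, conditional co-medication,
secondary-diagnosis placement, lookback-year records, coding-era
rollover — so the entire pipeline is testable end to end, with truth
labels, and no data access.

The bundled example is the retrospective rofecoxib (COX-2-selective
NSAID) case study: a criteria file transcribing the exclusion protocols
of its 14 pre-release trials, and reference count tables for the
year-2000 Western Australian 65+ arthritis cohort whose derived
percentages the test suite reproduces exactly. Bundled code lists are
illustrative placeholders, not curated clinical code sets.

## Worked example

```r
library(adewatch)

cs   <- example_codesets()
crit <- parse_criteria_file(rofecoxib_criteria_path())
excl <- aggregate_exclusions(crit, "OA",
                             c("musculoskeletal", "gastrointestinal"),
                             drug = "rofecoxib")

spec <- population_spec(n_persons = 5000, seed = 42)
gen  <- generate_population(spec, out_dir = "sim")
d    <- read_dispensing(gen$paths["dispensing"])
m    <- read_morbidity(gen$paths["morbidity"])

prof <- build_profiles(d, m, cs, cohort_config(2000))
table(classify_patient(prof[prof$has_target_med, ]))
#>      TARGET_ONLY TARGET_PLUS_FLAG
#>             1455             3203
table(merge_profiles(prof))
#>             MEDS_ONLY               DX_ONLY    MEDS_AND_TARGET_DX
#>                  2173                    33                   428
#> MEDS_AND_NONTARGET_DX
#>                  2057

compare_profiles(excl, prof, threshold = 10)
#> RISK ADVISORY: rofecoxib (indication: OA)
#> Cohort: persons aged >= 65 with target-morbidity evidence in 2000;
#>   merged cohort n = 4,691 (4,658 on target medication)
#> Flag threshold: prevalence >= 10%
#>
#> FLAGGED patient groups (trial-excluded factors prevalent in the real-world cohort):
#>   - CVD [CO_MEDICATION]: 3,203 of 4,658 patients (68.8%, medication
#>     evidence); excluded in 11 trial(s): OA-E01, ... [also 6.2% by
#>     diagnosis evidence, n = 4,691]
#> ...
#>   - HEPATIC [COMORBIDITY]: insufficient data (no cohort evidence computed); ...
```

Reading the output: 3,203 of the 4,658 synthetic target-medicated
patients (68.8%) are co-dispensed cardiovascular medication — the
generator's conditional co-medication probability recovered by the
pipeline — while every analysed efficacy trial excluded exactly those
patients, so the CVD group is flagged. Categories excluded in trials but
with no extractable cohort evidence (hepatic, neoplastic) surface as
"insufficient data" rather than disappearing.

A thin command-line interface wraps the same functions
(`inst/cli/adewatch.R` with subcommands `simulate`, `build-cohort`,
`profile`, `compare`; see the script header and
`inst/extdata/example_config.yaml`).

## Limitations

The advisory asserts the *absence of trial evidence*, not the presence of
harm; no statistical inference is attempted (the pipeline reports counts
and percentages, as its outputs are screening signals, not effect
estimates). Exclusion time windows ("stroke within 2 years prior") are
recorded and reported but not evaluated against patient-level event
dates. Inputs must arrive already person-linked; no probabilistic
linkage, and no automatic ICD-9↔ICD-10 mapping — per-era code lists are
the user's responsibility. See the methods vignette
(`vignettes/risk-pipeline.Rmd`) for the full model description and design
rationale.
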