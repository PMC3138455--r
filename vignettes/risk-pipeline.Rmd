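---
title: "Forecasting adverse-drug-event risk from trial exclusions and linked administrative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting adverse-drug-event risk from trial exclusions and linked administrative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Pre-marketing randomised trials buy internal validity with exclusion
protocols, and those protocols routinely remove the comorbidities and
co-medications that dominate older patients: cardiovascular,
cerebrovascular and renal disease, anticoagulant therapy, and so on. The
consequence is structural, not statistical — once every analysed trial
excluded a patient group, no amount of trial data describes the drug's
action in that group. Spontaneous ADE reporting then detects the damage
only after uptake, and is notoriously insensitive to increases in common
conditions such as cardiac disease.

`adewatch` operationalises a prospective alternative as a pure,
deterministic pipeline over two inputs that are available *before* wide
uptake:

1. a hand-curated, structured file of the trials' exclusion criteria,
   one row per criterion (`trial_id, indication, trial_type, domain,
   category, body_system, time_window_years, description`);
2. person-linked administrative records: pharmaceutical dispensing
   claims and hospital separations, as released by a data-linkage unit.

The comparison of the two is the model: a patient group is *at
potential risk* when a factor excluded across the trials is prevalent in
the drug's real-world target population. The output is a ranked,
threshold-flagged advisory; its epistemic claim is deliberately modest —
absence of evidence, never presence of harm.

### Question-specific versus other-system exclusions

Not all exclusions are equal. A gastric-safety trial excluding patients
with active gastric ulceration is exercising its own research question; a
pain-on-walking efficacy trial excluding patients who cannot walk is
doing the same. These are tagged per criterion with a `body_system` and
classified `QUESTION_SPECIFIC` when the tag falls among the analysis's
`target_systems`; everything else is `OTHER_SYSTEM`. Only other-system
exclusions feed the discordance score by default
(`include_question_specific = FALSE`), because question-specific
exclusions are legitimate design rather than evidence gaps. The
`target_systems` argument accepts several labels because a drug's trial
programme can pose questions in more than one system (the bundled
rofecoxib example uses `musculoskeletal` for the efficacy question and
`gastrointestinal` for the safety question).

### Cohort membership

For index year $Y$ (configurable, default 2000 in the bundled example) a
person is a member iff

* their maximum recorded age on an index-year record is at least
  `min_age` (years, default 65), and
* they carry index-year target evidence: a dispensing of a
  target-category item code, **or** a hospital separation whose primary
  *or any secondary* diagnosis matches a target code set.

Lookback records (default `lookback_years = 1`) are history only: a
person dispensed target medication solely in the lookback year is not a
member, because the prior-year extract exists to contextualise index-year
patients, not to extend the cohort. Medication *flag* evidence, by
contrast, may come from the index or lookback year — a cardiovascular
dispensing a few months before the index year still marks a
co-medicated patient.

### The two classification lattices

The medication dichotomy (`classify_patient()`) splits target-medicated
members into `TARGET_ONLY` vs `TARGET_PLUS_FLAG`, where a flag is *any*
flag-category medication. Diagnosis evidence plays no role here — the
dichotomy mirrors how co-prescription is summarised in drug-utilisation
analyses, and diagnosis-based comorbidity enters separately through the
cross-tab stage. The merged lattice (`merge_profiles()`) partitions the
merged cohort (medication members ∪ diagnosed members) into
`MEDS_ONLY`, `DX_ONLY`, `MEDS_AND_TARGET_DX`, `MEDS_AND_NONTARGET_DX`
with target-diagnosis precedence; the four classes are mutually
exclusive and exhaustive, and the package treats any violation as an
internal error rather than a data condition.

### Code matching and the coding-era rollover

ICD matching is dot-aware prefix matching: a set member matches itself
and any descendant with a dot boundary (`M15` matches `M15.0`, not
`M150X`). This is the right semantics for category-level code lists,
which name roots rather than enumerating leaves. Drug item codes match
exactly. All comparison is case-insensitive after trimming, since
administrative extracts vary in casing.

Australian hospital collections rolled over from ICD-9-CM to ICD-10-AM
mid-1999, and the rollover is a documented source of coding
inconsistency (notably in the application of secondary arthritis
diagnoses). The package therefore binds each diagnosis system to an era
(`default_code_systems()`: ICD-9-CM through 1999-06-30, ICD-10-AM from
1999-07-01) and *flags* era-inconsistent records — they are excluded
from diagnosis evidence and reported in the `era_flagged` attribute, but
never silently dropped and never remapped. Automatic
general-equivalence mapping across the rollover is explicitly a
non-goal: the safe response to inconsistent coding is exclusion with an
audit trail, and users supply per-era code lists.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_age` | 65 | years | the age gate of the target population |
| `lookback_years` | 1 | years | prior-year records as history |
| `high_use_threshold` | 3000 | dispensings | low-volume medications are noise for population-level profiling; target/flag code sets are always retained (`protected_codes()`) |
| `flag threshold` | 10 | % prevalence | flags discordance entries; no published numeric rule exists (the bundled exemplar's headline prevalence is 68.8%), so the threshold is prominent, configurable, and recorded in every advisory |
| age bands | 65-69 … 85-99 | — | five-year bands with an effectively open-ended top band (older ages clamp with a logged note) |

## Numerical choices

* **Rounding is half-up**, implemented as
  $\lfloor \mathrm{round}(10^d x, 9) + 0.5 \rfloor / 10^d$ — the inner
  9-digit round guards against decimally exact halves sitting an ulp
  below 0.5 in binary. Base R's `round()` is round-half-even and does
  not reproduce conventionally rounded published tables; the
  table-replication tests check every derived cell of the bundled
  reference tables under this rule.
* **Female share is the complement of the rounded male share**, so a
  printed ratio pair always sums to 100.
* **Prevalence denominators follow the evidence.** Medication evidence
  is a share of the target-medication cohort; diagnosis evidence a share
  of the merged cohort. When both exist for a category the advisory
  reports both, with denominators stated, and never pools them.
* **Ranking ties** break by domain order
  (`COMORBIDITY < CO_MEDICATION < DEMOGRAPHIC`), then category label,
  making advisories a pure function of their inputs.
* **Degenerate inputs**: an empty trial list yields an empty profile; an
  empty exclusion profile yields a well-formed advisory stating that no
  other-system exclusions were identified; an empty cohort is an error.
  Contradictory sex across a person's records resolves to the majority
  value (ties to the alphabetically first), flagged in `sex_conflict`.
  Age is the maximum recorded index-year age, since extracts carry age
  at service, not birth dates.
* **Time windows** ("stroke within 2 years prior") are aggregated to the
  tightest window across trials with the range noted, and inform
  advisory text only; evaluating them against patient-level event dates
  is out of scope for this version.

## What the synthetic generator emulates — and what it does not

`generate_population()` draws, per person: an age-band/sex cell
(defaults: the band-by-sex composition of the bundled reference
medication table), a target-medication Bernoulli (default 0.95), one
conditional co-medication Bernoulli per flag category given target
medication (default `c(CVD = 0.688)` — the bundled case study's headline
rate), target/flag/other hospital-diagnosis Bernoullis (defaults 0.087,
`c(CVD = 0.060, CVA = 0.011, RENAL = 0.009)`, 0.45 — chosen to echo the
reference morbidity and merged-lattice tables), lookback repetition
(0.6) and a small lookback-only rate (0.02) to exercise the
membership rule. Record-level structure includes uniform within-year
dates, diagnosis codes extended with dot-suffix children to exercise
hierarchical matching, placement of the coded condition in primary or
secondary fields with equal probability, and a geometric-rank
(heavy-tailed) pool of noise item codes so that a scaled-down high-use
threshold has bite. `calibrate_to_marginals()` inverts a count table
exactly: cell probabilities proportional to counts, and per-cell
conditional co-medication probabilities when the table carries the
dichotomy panels.

Deliberately *not* emulated: covariance between flag categories beyond
independent conditionals (published sources report marginals and a few
pairwise overlaps only), realistic item-code frequency distributions,
within-person longitudinal correlation of diagnoses, multiple
separations per hospitalisation episode, and any re-identification-risk
structure. Passing tests on synthetic data therefore demonstrate that
the pipeline's *logic* is correct under the generating assumptions — not
that real extracts are this clean. Real data add linkage error, coding
drift and duplicated records that the rejects report and era flags
surface but do not correct.

The mean dispensings per person-drug-year defaults to 3, well below the
~30 records/person-year of real extracts, purely to keep simulated files
small; prevalence estimates depend on persons, not records, so this
scaling does not bias the recovered rates.

## Verification strategy and problem sizes

The test suite runs three layers, all seeded and deterministic:

* **Table replication** — every derived percentage, ratio, subtotal and
  total of the bundled reference tables is recomputed exactly from the
  raw counts (58,968 medication-cohort rows reconstructed through the
  cross-tab machinery; all thirty sex-ratio cells).
* **Oracle equivalence** — membership, flags, both lattices, the
  high-use filter and cross-tab counts are compared against independent
  per-person loop re-implementations on 120-person populations across
  five seeds, including seeds with deliberate era mislabelling.
* **End-to-end reconstruction** — a 20,000-person population generated
  at the reference age/sex structure with 68.8% conditional CVD
  co-medication must come back through the full pipeline with the CVD
  co-medication entry flagged within three binomial standard errors of
  the generating rate, and with both lattices partitioning the cohort.
  Parameter-recovery tests additionally check 1,500-person populations
  across three seeds against 3-SE bounds, and a 100,000-person
  calibration run recovers the 65-69 band's co-medication share within
  one percentage point.

These sizes were chosen as the smallest at which binomial error bars are
tight enough for the checks to be meaningful.

## Known limitations

* Exclusion criteria are curated by hand; there is no scraping of
  registries or natural-language parsing of trial reports.
* The discordance threshold formalises a judgement the literature leaves
  qualitative; 10% is a screening default, not a validated cut-point.
* Demographic exclusions (age caps, sex restrictions) are carried
  through the profile but scored as "insufficient data" — evaluating
  them against the cohort's age structure is future work.
* Medicare/MBS services data, probabilistic linkage and cross-era code
  mapping are out of scope by design.
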