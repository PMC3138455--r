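#' Reference cross-tabulations from the bundled rofecoxib case study
#'
#' Published-style count tables from a retrospective case study of the
#' COX-2-selective NSAID rofecoxib: Western Australian patients aged 65
#' and over in the year-2000 cohort, profiled from linked PBS dispensing
#' and hospital morbidity data. The package ships the *counts* only; all
#' percentages, ratios, subtotals and totals are derived quantities that
#' [prevalence()], [sex_ratio()] and the cross-tab accessors recompute.
#'
#' Tables:
#' \describe{
#'   \item{medications_dichotomy}{`class, n` — target-only vs
#'     target-plus-CVD medication counts.}
#'   \item{medications_by_age_sex}{`band, panel, sex, n` — the dichotomy
#'     by age band and sex.}
#'   \item{morbidity_type}{`type, n` — hospital-diagnosed patients by
#'     target vs other morbidity.}
#'   \item{target_dx_by_age_sex}{`band, sex, n` — patients with a target
#'     (OA/RA) hospital diagnosis.}
#'   \item{merged_lattice}{`class, n` — the four-class merged
#'     medication/morbidity lattice.}
#'   \item{med_with_dx_by_age_sex}{`band, category, sex, n` — target
#'     medication plus CVD/CVA/renal hospital diagnosis.}
#'   \item{dx_with_dx_by_age_sex}{`band, category, sex, n` — target
#'     hospital diagnosis plus CVD/CVA/renal hospital diagnosis.}
#' }
#'
#' @return named list of tibbles with integer `n` columns.
#' @export
reference_tables <- function() {
  dir <- system.file("extdata", "tables", package = "adewatch",
                     mustWork = TRUE)
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  out <- lapply(files, function(f) {
    df <- as_tibble(read.csv(f, stringsAsFactors = FALSE))
    df$n <- as.integer(df$n)
    df
  })
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Path to the bundled rofecoxib trial-criteria file
#'
#' A curated transcription of the exclusion protocols applied in the
#' pre-release rofecoxib trials (eleven efficacy, two safety, one pooled):
#' cardiovascular, cerebrovascular, renal, hepatic and neoplastic
#' comorbidity exclusions, vascular co-medication exclusions, and the
#' question-specific gastrointestinal and mobility exclusions.
#'
#' @return file path, for [parse_criteria_file()].
#' @export
rofecoxib_criteria_path <- function() {
  system.file("extdata", "rofecoxib_criteria.csv", package = "adewatch",
              mustWork = TRUE)
}
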