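mk_profiles <- function(n = 100, p_med = 0.9, p_cvd = 0.6, seed = 41) {
  set.seed(seed)
  has_med <- runif(n) < p_med
  tibble::tibble(
    person_id = sprintf("P%03d", 1:n), age = 70L, age_band = "70-74",
    sex = sample(c("M", "F"), n, TRUE),
    has_target_med = has_med,
    has_target_dx = !has_med,
    has_hospital_dx = !has_med,
    med_CVD = has_med & runif(n) < p_cvd,
    dx_CVD = runif(n) < 0.05,
    med_CVA = FALSE, dx_CVA = runif(n) < 0.02,
    med_RENAL = FALSE, dx_RENAL = FALSE
  )
}

oa_exclusions <- function() {
  crit <- parse_criteria_file(rofecoxib_criteria_path())
  aggregate_exclusions(crit, "OA", c("musculoskeletal", "gastrointestinal"),
                       drug = "rofecoxib")
}

test_that("comparison scores every other-system category with stated denominators", {
  excl <- oa_exclusions()
  prof <- mk_profiles()
  adv <- compare_profiles(excl, prof, threshold = 10)
  e <- adv$entries
  # every OTHER_SYSTEM profile entry appears, flagged or not
  other <- dplyr::filter(as.data.frame(excl[c("domain", "category",
                                              "relevance")]),
                         relevance == "OTHER_SYSTEM")
  expect_identical(nrow(e), nrow(other))
  expect_false(any(e$category %in% c("GI_ULCER", "MOBILITY")))

  co_med <- e[e$domain == "CO_MEDICATION" & e$category == "CVD", ]
  expect_identical(co_med$evidence_source, "medication")
  expect_identical(co_med$denominator, sum(prof$has_target_med))
  expect_identical(co_med$cohort_count,
                   sum(prof$med_CVD & prof$has_target_med))
  expect_identical(co_med$cohort_prevalence,
                   prevalence(co_med$cohort_count, co_med$denominator, 1))
  expect_true(co_med$flagged)

  comorb <- e[e$domain == "COMORBIDITY" & e$category == "CVD", ]
  expect_identical(comorb$evidence_source, "diagnosis")
  expect_identical(comorb$denominator, nrow(prof))
  expect_identical(comorb$secondary_source, "medication")

  # unresolved categories surface as insufficient data, never dropped
  hep <- e[e$category == "HEPATIC", ]
  expect_identical(nrow(hep), 1L)
  expect_true(is.na(hep$cohort_prevalence))
  expect_false(hep$flagged)
  expect_match(hep$note, "insufficient data")

  expect_error(compare_profiles(excl, prof[0, ]), "empty cohort")
})

test_that("zero-carrier categories score prevalence 0 and empty profiles yield empty advisories", {
  excl <- oa_exclusions()
  prof <- mk_profiles()
  prof$dx_RENAL <- FALSE
  prof$med_RENAL <- FALSE
  adv <- compare_profiles(excl, prof)
  renal <- adv$entries[adv$entries$category == "RENAL", ]
  expect_identical(renal$cohort_prevalence, 0)
  expect_false(renal$flagged)

  crit <- parse_criteria_file(rofecoxib_criteria_path())
  empty_excl <- aggregate_exclusions(crit, "JIA", "musculoskeletal")
  adv0 <- compare_profiles(empty_excl, prof)
  expect_identical(nrow(adv0$entries), 0L)
  txt <- render_advisory(adv0, "text")
  expect_match(txt, "No other-body-system exclusion criteria")
})

test_that("flagging is threshold-monotone and never spontaneous", {
  excl <- oa_exclusions()
  prof <- mk_profiles()
  thresholds <- c(0, 5, 10, 50, 80, 100)
  flags <- vapply(thresholds, function(th) {
    sum(compare_profiles(excl, prof, threshold = th)$entries$flagged)
  }, integer(1))
  expect_true(all(diff(flags) <= 0))
  adv <- compare_profiles(excl, prof, threshold = 0)
  expect_true(all(adv$entries$category[adv$entries$flagged] %in%
                    excl$category))
})

test_that("entries rank by prevalence with the domain/category tie rule", {
  e <- tibble::tibble(
    category = c("B", "A", "C", "A2", "Z"),
    domain = c("CO_MEDICATION", "CO_MEDICATION", "COMORBIDITY",
               "COMORBIDITY", "DEMOGRAPHIC"),
    cohort_prevalence = c(12, 12, 12, 68.8, NA)
  )
  r <- rank_entries(e)
  expect_identical(r$category, c("A2", "C", "A", "B", "Z"))

  # random entries equal a naive full sort
  set.seed(42)
  n <- 20
  re <- tibble::tibble(
    category = sample(LETTERS, n),
    domain = sample(c("COMORBIDITY", "CO_MEDICATION", "DEMOGRAPHIC"),
                    n, TRUE),
    cohort_prevalence = sample(c(NA, round(runif(5) * 100, 1)), n, TRUE)
  )
  want <- re[order(is.na(re$cohort_prevalence),
                   -ifelse(is.na(re$cohort_prevalence), 0,
                           re$cohort_prevalence),
                   match(re$domain, c("COMORBIDITY", "CO_MEDICATION",
                                      "DEMOGRAPHIC")),
                   re$category), ]
  expect_identical(rank_entries(re), want)
})

test_that("advisories render deterministically in both formats", {
  excl <- oa_exclusions()
  prof <- mk_profiles()
  adv <- compare_profiles(excl, prof)
  t1 <- render_advisory(adv, "text")
  t2 <- render_advisory(adv, "text")
  expect_identical(t1, t2)
  expect_match(t1, "rofecoxib")
  expect_match(t1, "monitor")
  expect_match(t1, "CVD \\[CO_MEDICATION\\]")

  s <- render_advisory(adv, "structured")
  expect_identical(s$drug, "rofecoxib")
  expect_identical(length(s$entries), nrow(adv$entries))
  j1 <- jsonlite::toJSON(s, auto_unbox = TRUE)
  j2 <- jsonlite::toJSON(render_advisory(adv, "structured"),
                         auto_unbox = TRUE)
  expect_identical(j1, j2)
})
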