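write_tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("readers validate rows into records and a rejects report", {
  d <- data.frame(person_id = c("P1", "P2", "P3", "P4", "P5"),
                  dispense_date = c("2000-01-02", "bad", "2000-03-04",
                                    "2000-05-06", "2000-07-08"),
                  item_code = c("10101", "10101", "10101", "10101", "10101"),
                  age = c(70, 71, 72, -1, 74),
                  sex = c("F", "M", "F", "M", "X"))
  r <- read_dispensing(write_tmp_csv(d))
  expect_identical(nrow(r$records), 2L)
  expect_identical(nrow(r$rejects), 3L)
  expect_setequal(r$rejects$reason,
                  c("unparseable dispense_date", "invalid age",
                    "invalid sex"))

  m <- data.frame(person_id = "P1", separation_date = "2000-02-03",
                  system = "ICD10AM", primary_dx = "M15.1",
                  secondary_dx = "I21; N18.9 ", age = 70, sex = "F")
  rm <- read_morbidity(write_tmp_csv(m))
  expect_identical(nrow(rm$records), 1L)
  expect_identical(rm$records$secondary_dx[[1]], c("I21", "N18.9"))

  # empty file with header
  r0 <- read_dispensing(write_tmp_csv(d[0, ]))
  expect_identical(nrow(r0$records), 0L)

  expect_error(read_dispensing(write_tmp_csv(d[, -3])), "missing required")
})

test_that("high-use filter keeps items at the threshold and protected codes", {
  d <- bind_rows(
    disp_row(sprintf("A%04d", 1:3000), "2000-01-01", "77777", 70),
    disp_row(sprintf("B%04d", 1:2999), "2000-01-01", "88888", 70),
    disp_row("C1", "2000-01-01", "10101", 70)
  )
  f <- high_use_filter(d, 3000)
  expect_identical(f$dropped_item_codes, c("10101", "88888"))
  expect_identical(sort(unique(f$kept$item_code)), "77777")

  fp <- high_use_filter(d, 3000, protected = protected_codes(CS, CFG))
  expect_identical(fp$dropped_item_codes, "88888")

  expect_identical(nrow(high_use_filter(d, 0)$kept), nrow(d))
})

test_that("high-use filter equals a naive count-then-filter oracle", {
  set.seed(21)
  for (s in 1:3) {
    d <- disp_row(sprintf("P%03d", sample(50, 100, TRUE)), "2000-06-01",
                  sample(c("A1", "B2", "C3", "D4", "E5"), 100, TRUE,
                         prob = c(.4, .3, .15, .1, .05)), 70)
    f <- high_use_filter(d, 5)
    tab <- table(d$item_code)
    naive_drop <- sort(names(tab)[tab < 5])
    expect_identical(f$dropped_item_codes, naive_drop)
    expect_identical(nrow(f$kept), sum(!d$item_code %in% naive_drop))
  }
})

test_that("cohort membership follows the index-year evidence rules", {
  d <- bind_rows(
    disp_row("P1", "2000-03-01", "10101", 70),   # target med, index year
    disp_row("P3", "2000-03-01", "10101", 64),   # under age gate
    disp_row("P4", "1999-03-01", "10101", 69),   # lookback only
    disp_row("P5", "2000-03-01", "N9001", 70),   # non-target item
    disp_row("P6", "1999-06-01", "10102", 71)    # history for P6
  )
  m <- bind_rows(
    morb_row("P2", "2000-04-01", "J18", c("K21", "M15.1")),  # target in secondary
    morb_row("P6", "2000-05-01", "M16"),                     # target primary
    morb_row("P7", "2000-05-01", "J18")                      # no target code
  )
  ids <- identify_target_cohort(d, m, CS, CFG)
  expect_identical(ids, c("P1", "P2", "P6"))

  prof <- build_profiles(d, m, CS, CFG)
  expect_identical(prof$person_id, ids)
  expect_true(all(prof$has_target_med | prof$has_target_dx))
  expect_identical(prof$has_target_med, c(TRUE, FALSE, FALSE))
  # P6's lookback dispensing is history, not membership evidence
  expect_false(prof$has_target_med[prof$person_id == "P6"])
})

test_that("era-flagged morbidity records are reported and excluded from evidence", {
  m <- bind_rows(
    morb_row("P1", "2000-04-01", "M15"),                      # valid
    morb_row("P2", "2000-04-01", "715.1", system = "ICD9CM")  # after rollover
  )
  prof <- build_profiles(empty_disp(), m, CS, CFG)
  expect_identical(prof$person_id, "P1")
  flagged <- attr(prof, "era_flagged")
  expect_identical(flagged$person_id, "P2")
})

test_that("contradictory sex is resolved by majority and flagged", {
  d <- bind_rows(
    disp_row("P1", "2000-01-01", "10101", 70, "M"),
    disp_row("P1", "2000-02-01", "10101", 70, "M"),
    disp_row("P1", "2000-03-01", "10101", 71, "F")
  )
  expect_message(prof <- build_profiles(d, empty_morb(), CS, CFG),
                 "contradictory sex")
  expect_identical(prof$sex, "M")
  expect_true(prof$sex_conflict)
  expect_identical(prof$age, 71L)  # max recorded index-year age
})

test_that("the medication dichotomy follows medication evidence only", {
  combos <- expand.grid(med_CVD = c(FALSE, TRUE), med_CVA = c(FALSE, TRUE),
                        dx_CVD = c(FALSE, TRUE))
  prof <- tibble(person_id = sprintf("P%d", 1:8), age = 70L,
                 age_band = "70-74", sex = "F", has_target_med = TRUE,
                 has_target_dx = FALSE, has_hospital_dx = combos$dx_CVD,
                 med_CVD = combos$med_CVD, med_CVA = combos$med_CVA,
                 dx_CVD = combos$dx_CVD)
  cls <- classify_patient(prof)
  # exhaustive truth table: flag iff any medication flag, dx plays no part
  expect_identical(as.character(cls),
                   ifelse(combos$med_CVD | combos$med_CVA,
                          "TARGET_PLUS_FLAG", "TARGET_ONLY"))
  expect_identical(sum(cls == "TARGET_ONLY") +
                     sum(cls == "TARGET_PLUS_FLAG"), nrow(prof))

  expect_error(classify_patient(dplyr::mutate(prof, has_target_med = FALSE)),
               "target medication")
})

test_that("the merged lattice is a partition with the documented precedence", {
  prof <- tibble(
    person_id = sprintf("P%d", 1:4), age = 70L, age_band = "70-74",
    sex = "F",
    has_target_med = c(TRUE, FALSE, TRUE, TRUE),
    has_target_dx = c(FALSE, TRUE, TRUE, FALSE),
    has_hospital_dx = c(FALSE, TRUE, TRUE, TRUE)
  )
  cls <- merge_profiles(prof)
  expect_identical(as.character(cls),
                   c("MEDS_ONLY", "DX_ONLY", "MEDS_AND_TARGET_DX",
                     "MEDS_AND_NONTARGET_DX"))
  expect_identical(sum(table(cls)), nrow(prof))

  # a 50-person random fixture equals brute-force set-membership tests
  set.seed(22)
  n <- 50
  rp <- tibble(
    person_id = sprintf("Q%03d", 1:n), age = 70L, age_band = "70-74",
    sex = "F",
    has_target_med = sample(c(TRUE, FALSE), n, TRUE, c(.8, .2)),
    has_target_dx = sample(c(TRUE, FALSE), n, TRUE, c(.3, .7)),
    has_hospital_dx = sample(c(TRUE, FALSE), n, TRUE)
  )
  rp$has_target_dx[!rp$has_target_med] <- TRUE          # must be members
  rp$has_hospital_dx[rp$has_target_dx] <- TRUE          # dx implies a record
  got <- as.character(merge_profiles(rp))
  want <- mapply(function(med, tdx, hosp) {
    if (med && tdx) "MEDS_AND_TARGET_DX"
    else if (med && hosp) "MEDS_AND_NONTARGET_DX"
    else if (med) "MEDS_ONLY" else "DX_ONLY"
  }, rp$has_target_med, rp$has_target_dx, rp$has_hospital_dx)
  expect_identical(got, unname(want))
  expect_identical(sum(table(merge_profiles(rp))), as.integer(n))
})

test_that("membership is monotone under record addition", {
  set.seed(23)
  gen <- generate_population(population_spec(60, seed = 31,
                                             p_target_med = 0.5,
                                             p_target_dx = 0.3))
  io <- read_generated(gen)
  base <- identify_target_cohort(io$dispensing, io$morbidity, CS, CFG)
  extra <- bind_rows(io$dispensing$records,
                     disp_row("ZZZ1", "2000-05-05", "10101", 80))
  grown <- identify_target_cohort(extra, io$morbidity, CS, CFG)
  expect_true(all(base %in% grown))
  expect_true("ZZZ1" %in% grown)
})
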