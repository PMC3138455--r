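test_that("population specs validate probabilities and weights", {
  expect_error(population_spec(100, p_target_med = 1.2), "\\[0, 1\\]")
  expect_error(population_spec(100, p_flag_dx = c(CVD = -0.1)), "\\[0, 1\\]")
  expect_error(population_spec(0), "n_persons >= 1")
  w <- tibble::tibble(band = "65-69", sex = "F", weight = 0)
  expect_error(population_spec(100, age_sex_weights = w), "positive total")
})

test_that("generation is seed-deterministic and seed-sensitive", {
  spec <- population_spec(150, seed = 5)
  g1 <- generate_population(spec)
  g2 <- generate_population(spec)
  expect_identical(g1, g2)
  g3 <- generate_population(spec, seed = 6)
  expect_false(identical(g1$dispensing, g3$dispensing))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_population(spec, out_dir = d1)
  generate_population(spec, out_dir = d2)
  for (f in c("dispensing.csv", "morbidity.csv", "truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("generated files pass the readers with zero rejects unless injected", {
  gen <- generate_population(population_spec(200, seed = 8))
  io <- read_generated(gen)
  expect_identical(nrow(io$dispensing$rejects), 0L)
  expect_identical(nrow(io$morbidity$rejects), 0L)

  genr <- generate_population(population_spec(200, seed = 8,
                                              p_reject = 0.05))
  ior <- read_generated(genr)
  expect_gt(nrow(ior$dispensing$rejects), 0)
  expect_true(all(ior$dispensing$rejects$reason ==
                    "unparseable dispense_date"))
})

test_that("degenerate probabilities produce the pure TARGET_ONLY cohort", {
  spec <- population_spec(120, seed = 9, p_target_med = 1,
                          p_flag_med_given_target = 0,
                          p_lookback_only = 0, p_target_dx = 0,
                          p_other_dx = 0, p_flag_dx = c(CVD = 0))
  gen <- generate_population(spec)
  expect_true(all(gen$truth$med_class == "TARGET_ONLY"))
  io <- read_generated(gen)
  prof <- build_profiles(io$dispensing, io$morbidity, CS, CFG)
  expect_identical(nrow(prof), 120L)
  expect_true(all(classify_patient(prof) == "TARGET_ONLY"))
})

test_that("truth labels agree with the pipeline classification on noise-free specs", {
  for (s in c(101, 102)) {
    gen <- generate_population(population_spec(400, seed = s))
    io <- read_generated(gen)
    prof <- build_profiles(io$dispensing, io$morbidity, CS, CFG)
    truth <- gen$truth[gen$truth$in_cohort, ]
    expect_identical(prof$person_id, truth$person_id)
    merged <- as.character(merge_profiles(prof))
    agree <- mean(merged == truth$merged_class)
    expect_gte(agree, 0.999)
    med <- prof[prof$has_target_med, ]
    tmed <- truth[truth$target_med & !truth$lookback_only, ]
    expect_identical(as.character(classify_patient(med)), tmed$med_class)
  }
})

test_that("era-inconsistent coding labels are flagged, reducing but bounding truth agreement", {
  spec <- population_spec(300, seed = 11,
                          era_mix = c(ICD9CM = 0.5, ICD10AM = 0.5))
  gen <- generate_population(spec)
  io <- read_generated(gen)
  prof <- build_profiles(io$dispensing, io$morbidity, CS, CFG)
  flagged <- attr(prof, "era_flagged")
  # index year 2000 is entirely in the ICD-10-AM era
  expect_gt(nrow(flagged), 0)
  expect_true(all(flagged$system == "ICD9CM"))
  expect_identical(nrow(flagged) + sum(io$morbidity$records$system ==
                                         "ICD10AM"),
                   nrow(io$morbidity$records))
})

test_that("pipeline-estimated prevalences recover spec probabilities within 3 SE", {
  p_cvd <- 0.688
  for (s in c(201, 202, 203)) {
    gen <- generate_population(population_spec(1500, seed = s))
    io <- read_generated(gen)
    prof <- build_profiles(io$dispensing, io$morbidity, CS, CFG)
    med <- prof[prof$has_target_med, ]
    est <- mean(med$med_CVD)
    se <- sqrt(p_cvd * (1 - p_cvd) / nrow(med))
    expect_lt(abs(est - p_cvd), 3 * se)
  }
})

test_that("marginal calibration reproduces target cell structure", {
  # single-cell target puts every person in that cell
  one <- tibble::tibble(band = "70-74", sex = "M", n = 50)
  spec1 <- calibrate_to_marginals(one, seed = 12)
  gen1 <- generate_population(spec1)
  expect_identical(nrow(gen1$truth), 50L)
  expect_true(all(gen1$truth$age_band == "70-74" & gen1$truth$sex == "M"))

  # uniform 2x2 target recovers 25% shares within 3 multinomial SE
  u <- tidyr::expand_grid(band = c("65-69", "70-74"), sex = c("M", "F"))
  u$n <- 25
  spec2 <- calibrate_to_marginals(u, n_persons = 2000, seed = 13)
  gen2 <- generate_population(spec2)
  shares <- table(gen2$truth$age_band, gen2$truth$sex) / 2000
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_true(all(abs(as.numeric(shares) - 0.25) < 3 * se))

  expect_error(calibrate_to_marginals(dplyr::mutate(one, n = 0)),
               "zero-total")
})

test_that("calibrating to the reference dichotomy recovers its per-band co-medication shares", {
  t2 <- reference_tables()$medications_by_age_sex
  spec <- calibrate_to_marginals(t2, n_persons = 100000, seed = 14,
                                 p_target_dx = 0, p_other_dx = 0,
                                 p_flag_dx = c(CVD = 0),
                                 mean_noise_drugs = 0)
  gen <- generate_population(spec)
  truth <- gen$truth
  # 61% of the 65-69 band carries flag co-medication in the target table
  b1 <- truth[truth$age_band == "65-69", ]
  expect_lt(abs(mean(b1$med_CVD) - 0.61), 0.01)
  # and the overall share matches the table's 40,595 / 58,968
  expect_lt(abs(mean(truth$med_CVD) - 40595 / 58968), 0.01)
})
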