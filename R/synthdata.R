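#' @title Synthetic person-level linked data
#' @description Real linked dispensing and hospital-morbidity extracts are
#'   released only by data-linkage units and are not redistributable, so
#'   the package ships a seeded generator that emulates their statistical
#'   structure: configurable age/sex composition, target-medication and
#'   target-diagnosis prevalence, conditional flag-category co-medication
#'   (one Bernoulli per category given target medication), per-category
#'   hospital diagnosis rates, previous-year (lookback) records, a
#'   heavy-tailed mass of low-frequency noise item codes to give the
#'   high-use filter bite at reduced scale, and optional coding-era
#'   mislabelling to exercise the rollover check. Every generated person's
#'   generating-class labels are recorded in a truth table against which
#'   the pipeline's classification can be verified.
#' @name synthdata
NULL

check_prob <- function(p, what) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("population_spec(): ", what, " must be within [0, 1]")
  }
  p
}

#' Specify a synthetic population
#'
#' Defaults emulate the bundled year-2000 arthritis case study: the
#' age/sex composition of the reference medication table, 68.8% CVD
#' co-medication among target-medicated persons, and diagnosis rates
#' echoing the reference morbidity tables.
#'
#' @param n_persons number of persons (>= 1).
#' @param index_year cohort index year (default 2000).
#' @param seed default RNG seed used by [generate_population()].
#' @param bands age bands, see [default_age_bands()].
#' @param age_sex_weights tibble `band, sex, weight`; defaults to the
#'   band-by-sex totals of the bundled reference medication table.
#' @param flag_cell_probs optional tibble `band, sex, p` giving a
#'   per-cell conditional co-medication probability for the *first* flag
#'   category, overriding its scalar probability (used by
#'   [calibrate_to_marginals()]).
#' @param p_target_med probability a person is dispensed a target
#'   medication.
#' @param p_flag_med_given_target named vector: probability of
#'   flag-category co-medication given target medication (an unnamed
#'   scalar applies to `"CVD"`). Default `c(CVD = 0.688)`.
#' @param p_target_dx probability of an index-year hospital separation
#'   carrying a target diagnosis.
#' @param p_flag_dx named vector of per-category hospital-diagnosis
#'   probabilities.
#' @param p_other_dx probability of an index-year hospital separation with
#'   unrelated diagnoses only.
#' @param p_lookback_record probability a person's medications also appear
#'   in the lookback year.
#' @param p_lookback_only probability a target-medicated person's target
#'   dispensings fall in the lookback year only (history, not a member).
#' @param mean_dispensings mean dispensings per person-drug-year.
#' @param mean_noise_drugs mean number of distinct noise (non-target,
#'   non-flag) drugs per person.
#' @param n_noise_items size of the noise item-code pool.
#' @param noise_decay geometric decay of noise item-code popularity by
#'   rank, in (0, 1); smaller values concentrate dispensings on few codes.
#' @param era_mix optional named probability vector over coding systems
#'   (`ICD9CM`, `ICD10AM`) used to label morbidity records; the default
#'   `NULL` labels each record with the era-correct system for its date.
#'   Deliberately era-inconsistent labels exercise the rollover check.
#' @param p_reject probability a dispensing row is written with a
#'   malformed date, to exercise the readers' rejects report.
#' @return an object of class `adw_population_spec`.
#' @export
population_spec <- function(n_persons,
                            index_year = 2000L,
                            seed = 1L,
                            bands = default_age_bands(),
                            age_sex_weights = NULL,
                            flag_cell_probs = NULL,
                            p_target_med = 0.95,
                            p_flag_med_given_target = c(CVD = 0.688),
                            p_target_dx = 0.087,
                            p_flag_dx = c(CVD = 0.060, CVA = 0.011,
                                          RENAL = 0.009),
                            p_other_dx = 0.45,
                            p_lookback_record = 0.6,
                            p_lookback_only = 0.02,
                            mean_dispensings = 3,
                            mean_noise_drugs = 2,
                            n_noise_items = 40L,
                            noise_decay = 0.85,
                            era_mix = NULL,
                            p_reject = 0) {
  n_persons <- as.integer(n_persons)
  stopifnot(length(n_persons) == 1, n_persons >= 1)
  if (is.null(age_sex_weights)) {
    t2 <- reference_tables()$medications_by_age_sex
    age_sex_weights <- t2 |>
      group_by(.data$band, .data$sex) |>
      summarise(weight = sum(.data$n), .groups = "drop")
  }
  require_columns(age_sex_weights, c("band", "sex", "weight"),
                  "age_sex_weights")
  if (sum(age_sex_weights$weight) <= 0) {
    stop("population_spec(): age_sex_weights must have positive total")
  }
  if (!all(age_sex_weights$band %in% bands$label)) {
    stop("population_spec(): age_sex_weights band(s) not in bands")
  }
  age_sex_weights$weight <- age_sex_weights$weight /
    sum(age_sex_weights$weight)
  if (is.null(names(p_flag_med_given_target))) {
    stopifnot(length(p_flag_med_given_target) == 1)
    p_flag_med_given_target <- c(CVD = unname(p_flag_med_given_target))
  }
  check_prob(c(p_target_med, p_flag_med_given_target, p_target_dx,
               p_flag_dx, p_other_dx, p_lookback_record, p_lookback_only,
               p_reject), "probabilities")
  if (!is.null(flag_cell_probs)) {
    require_columns(flag_cell_probs, c("band", "sex", "p"),
                    "flag_cell_probs")
    check_prob(flag_cell_probs$p, "flag_cell_probs$p")
  }
  if (!is.null(era_mix)) {
    stopifnot(!is.null(names(era_mix)),
              all(names(era_mix) %in% c("ICD9CM", "ICD10AM")),
              sum(era_mix) > 0)
    era_mix <- era_mix / sum(era_mix)
  }
  stopifnot(mean_dispensings >= 1, mean_noise_drugs >= 0,
            n_noise_items >= 1, noise_decay > 0, noise_decay < 1)
  structure(list(
    n_persons = n_persons, index_year = as.integer(index_year),
    seed = as.integer(seed), bands = bands,
    age_sex_weights = age_sex_weights, flag_cell_probs = flag_cell_probs,
    p_target_med = p_target_med,
    p_flag_med_given_target = p_flag_med_given_target,
    p_target_dx = p_target_dx, p_flag_dx = p_flag_dx,
    p_other_dx = p_other_dx, p_lookback_record = p_lookback_record,
    p_lookback_only = p_lookback_only,
    mean_dispensings = mean_dispensings,
    mean_noise_drugs = mean_noise_drugs,
    n_noise_items = as.integer(n_noise_items), noise_decay = noise_decay,
    era_mix = era_mix, p_reject = p_reject
  ), class = "adw_population_spec")
}

#' @export
print.adw_population_spec <- function(x, ...) {
  cat("<population spec: ", fmt_n(x$n_persons), " persons, index year ",
      x$index_year, ", seed ", x$seed, ">\n",
      " p(target med) = ", x$p_target_med,
      "; p(flag med | target) = ",
      paste(names(x$p_flag_med_given_target),
            x$p_flag_med_given_target, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

rand_day <- function(year, n) {
  format(as.Date(paste0(year, "-01-01")) + sample.int(365, n, TRUE) - 1L,
         "%Y-%m-%d")
}

# draw record-level ICD codes for a category: a set member, sometimes
# extended with a dot-suffix child to exercise hierarchical matching
draw_icd <- function(n, category, system_name, codesets) {
  codes <- codes_for(codesets, category, system_name)
  if (length(codes) == 0) {
    stop("no ", system_name, " code set for category ", category)
  }
  base <- codes[sample.int(length(codes), n, TRUE)]
  extend <- runif(n) < 0.5 & !grepl("\\.", base)
  base[extend] <- paste0(base[extend], ".", sample(0:9, sum(extend), TRUE))
  base
}

FILLER_DX <- list(
  ICD10AM = c("J18", "E11", "K21", "H25", "L40", "F32"),
  ICD9CM = c("486", "250", "530", "366", "696", "311")
)

era_correct_system <- function(dates,
                               systems = default_code_systems()) {
  ifelse(as.Date(dates) >= systems$ICD10AM$era_start, "ICD10AM", "ICD9CM")
}

#' Generate a synthetic linked population
#'
#' Draws persons, dispensing records and hospital morbidity records from a
#' [population_spec()], returning file-shaped tibbles (character ISO
#' dates, semicolon-delimited secondary diagnoses) that conform to the
#' cohort module's input formats, plus a truth table of each person's
#' generating-class labels. The same seed always yields byte-identical
#' output.
#'
#' @param spec a [population_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @param out_dir optional directory; when given, writes
#'   `dispensing.csv`, `morbidity.csv` and `truth.csv`.
#' @param codesets code sets supplying item and diagnosis codes
#'   (default [example_codesets()]).
#' @param target_categories code-set categories defining the target
#'   morbidity (default `c("OA", "RA")`).
#' @return list with tibbles `dispensing`, `morbidity`, `truth` (and
#'   `paths` when `out_dir` is given).
#' @export
generate_population <- function(spec, seed = NULL, out_dir = NULL,
                                codesets = example_codesets(),
                                target_categories = c("OA", "RA")) {
  stopifnot(inherits(spec, "adw_population_spec"))
  set.seed(seed %||% spec$seed)
  n <- spec$n_persons
  idx_year <- spec$index_year
  lb_year <- idx_year - 1L

  med_cats <- names(spec$p_flag_med_given_target)
  dx_cats <- names(spec$p_flag_dx)

  ## persons
  cells <- spec$age_sex_weights
  ci <- sample.int(nrow(cells), n, TRUE, prob = cells$weight)
  band <- cells$band[ci]
  sex <- cells$sex[ci]
  bdef <- spec$bands
  lo <- bdef$lower[match(band, bdef$label)]
  hi <- bdef$upper[match(band, bdef$label)]
  age <- lo + floor(runif(n) * (hi - lo + 1L))
  person_id <- sprintf("P%06d", seq_len(n))

  target_med <- runif(n) < spec$p_target_med
  lookback_only <- target_med & runif(n) < spec$p_lookback_only

  med_flag <- matrix(FALSE, n, length(med_cats),
                     dimnames = list(NULL, med_cats))
  for (k in seq_along(med_cats)) {
    cat_k <- med_cats[k]
    p <- rep(spec$p_flag_med_given_target[[cat_k]], n)
    if (k == 1L && !is.null(spec$flag_cell_probs)) {
      key <- paste(band, sex)
      fc <- spec$flag_cell_probs
      p <- fc$p[match(key, paste(fc$band, fc$sex))]
      p[is.na(p)] <- spec$p_flag_med_given_target[[cat_k]]
    }
    med_flag[, k] <- target_med & runif(n) < p
  }

  target_dx <- runif(n) < spec$p_target_dx
  dx_flag <- matrix(FALSE, n, length(dx_cats),
                    dimnames = list(NULL, dx_cats))
  for (k in seq_along(dx_cats)) {
    dx_flag[, k] <- runif(n) < spec$p_flag_dx[[dx_cats[k]]]
  }
  other_dx <- runif(n) < spec$p_other_dx

  ## dispensing: assemble the per-person drug repertoire
  target_items <- codes_for(codesets, target_categories, "DRUG_ITEM")
  if (length(target_items) == 0) stop("no target DRUG_ITEM codes supplied")
  drugs <- list()
  who <- which(target_med)
  if (length(who)) {
    drugs[["t1"]] <- tibble(
      pidx = who,
      item = target_items[sample.int(length(target_items),
                                     length(who), TRUE)]
    )
    second <- who[runif(length(who)) < 0.4]
    if (length(second)) {
      drugs[["t2"]] <- tibble(
        pidx = second,
        item = target_items[sample.int(length(target_items),
                                       length(second), TRUE)]
      )
    }
  }
  for (cat_k in med_cats) {
    items <- codes_for(codesets, cat_k, "DRUG_ITEM")
    if (length(items) == 0) {
      stop("no DRUG_ITEM code set for flag category ", cat_k)
    }
    who <- which(med_flag[, cat_k])
    if (length(who)) {
      drugs[[paste0("f_", cat_k)]] <- tibble(
        pidx = who,
        item = items[sample.int(length(items), length(who), TRUE)]
      )
    }
  }
  noise_pool <- sprintf("N9%03d", seq_len(spec$n_noise_items))
  noise_w <- spec$noise_decay^(seq_len(spec$n_noise_items) - 1)
  k_noise <- rpois(n, spec$mean_noise_drugs)
  if (sum(k_noise) > 0) {
    drugs[["noise"]] <- tibble(
      pidx = rep(seq_len(n), k_noise),
      item = noise_pool[sample.int(length(noise_pool), sum(k_noise), TRUE,
                                   prob = noise_w)]
    )
  }
  drugs <- bind_rows(drugs)
  if (nrow(drugs) == 0) {
    drugs <- tibble(pidx = integer(0), item = character(0))
  }
  drugs <- arrange(distinct(drugs), .data$pidx, .data$item)

  in_index <- !lookback_only[drugs$pidx]
  in_lb <- lookback_only[drugs$pidx] |
    runif(nrow(drugs)) < spec$p_lookback_record
  expand_year <- function(sel, year) {
    rows <- which(sel)
    if (!length(rows)) {
      return(tibble(person_id = character(0), dispense_date = character(0),
                    item_code = character(0), age = integer(0),
                    sex = character(0)))
    }
    cnt <- 1L + rpois(length(rows), spec$mean_dispensings - 1)
    pid <- rep(drugs$pidx[rows], cnt)
    tibble(
      person_id = person_id[pid],
      dispense_date = rand_day(year, length(pid)),
      item_code = rep(drugs$item[rows], cnt),
      age = as.integer(if (year == idx_year) age[pid]
                       else pmax(age[pid] - 1L, 0L)),
      sex = sex[pid]
    )
  }
  dispensing <- bind_rows(expand_year(in_index, idx_year),
                          expand_year(in_lb, lb_year))
  dispensing <- arrange(dispensing, .data$person_id, .data$dispense_date,
                        .data$item_code)
  if (spec$p_reject > 0 && nrow(dispensing) > 0) {
    bad <- runif(nrow(dispensing)) < spec$p_reject
    dispensing$dispense_date[bad] <- "not-a-date"
  }

  ## morbidity events (index year)
  events <- list()
  add_event <- function(who, category) {
    if (!length(who)) return(NULL)
    dates <- rand_day(idx_year, length(who))
    systems <- if (is.null(spec$era_mix)) {
      era_correct_system(dates)
    } else {
      names(spec$era_mix)[sample.int(length(spec$era_mix), length(who),
                                     TRUE, prob = spec$era_mix)]
    }
    main <- character(length(who))
    for (sysn in unique(systems)) {
      s <- systems == sysn
      main[s] <- if (is.na(category)) {
        FILLER_DX[[sysn]][sample.int(length(FILLER_DX[[sysn]]),
                                     sum(s), TRUE)]
      } else {
        draw_icd(sum(s), category, sysn, codesets)
      }
    }
    filler <- vapply(seq_along(who), function(i) {
      pool <- FILLER_DX[[systems[i]]]
      paste(pool[sample.int(length(pool), sample(0:2, 1))], collapse = ";")
    }, character(1))
    # the coded condition lands in the primary field or a secondary field
    in_primary <- runif(length(who)) < 0.5 | !nzchar(filler)
    primary <- ifelse(in_primary, main,
                      vapply(strsplit(filler, ";"), `[`, character(1), 1))
    secondary <- ifelse(in_primary, filler,
                        vapply(seq_along(who), function(i) {
                          rest <- strsplit(filler[i], ";")[[1]][-1]
                          paste(c(rest, main[i]), collapse = ";")
                        }, character(1)))
    tibble(
      person_id = person_id[who], separation_date = dates,
      system = systems, primary_dx = primary, secondary_dx = secondary,
      age = as.integer(age[who]), sex = sex[who]
    )
  }
  tcat <- intersect(target_categories, codeset_categories(codesets))
  who_t <- which(target_dx)
  if (length(who_t)) {
    pick <- tcat[sample.int(length(tcat), length(who_t), TRUE)]
    for (ct in unique(pick)) {
      events[[paste0("t_", ct)]] <- add_event(who_t[pick == ct], ct)
    }
  }
  for (cat_k in dx_cats) {
    events[[paste0("d_", cat_k)]] <- add_event(which(dx_flag[, cat_k]),
                                               cat_k)
  }
  events[["other"]] <- add_event(which(other_dx), NA)
  morbidity <- bind_rows(events)
  if (nrow(morbidity) == 0) {
    morbidity <- tibble(
      person_id = character(0), separation_date = character(0),
      system = character(0), primary_dx = character(0),
      secondary_dx = character(0), age = integer(0), sex = character(0)
    )
  }
  morbidity <- arrange(morbidity, .data$person_id, .data$separation_date,
                       .data$primary_dx)

  ## truth
  member_med <- target_med & !lookback_only
  in_cohort <- member_med | target_dx
  any_flag_med <- rowSums(med_flag) > 0
  has_hospital <- target_dx | other_dx | rowSums(dx_flag) > 0
  med_class <- ifelse(!member_med, NA_character_,
                      ifelse(any_flag_med, "TARGET_PLUS_FLAG",
                             "TARGET_ONLY"))
  merged_class <- ifelse(!in_cohort, NA_character_,
                  ifelse(member_med & target_dx, "MEDS_AND_TARGET_DX",
                  ifelse(member_med & has_hospital, "MEDS_AND_NONTARGET_DX",
                  ifelse(member_med, "MEDS_ONLY", "DX_ONLY"))))
  truth <- tibble(
    person_id = person_id, age = as.integer(age), age_band = band,
    sex = sex, target_med = target_med, lookback_only = lookback_only,
    target_dx = target_dx, other_dx = other_dx,
    in_cohort = in_cohort, med_class = med_class,
    merged_class = merged_class
  )
  for (cat_k in med_cats) truth[[paste0("med_", cat_k)]] <- med_flag[, cat_k]
  for (cat_k in dx_cats) truth[[paste0("dx_", cat_k)]] <- dx_flag[, cat_k]

  out <- list(dispensing = dispensing, morbidity = morbidity, truth = truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- file.path(out_dir, c("dispensing.csv", "morbidity.csv",
                                  "truth.csv"))
    write.csv(as.data.frame(dispensing), paths[1], row.names = FALSE)
    write.csv(as.data.frame(morbidity), paths[2], row.names = FALSE)
    write.csv(as.data.frame(truth), paths[3], row.names = FALSE)
    out$paths <- setNames(paths, c("dispensing", "morbidity", "truth"))
  }
  out
}

#' Calibrate a population spec to target marginal counts
#'
#' Builds a spec whose expected per-cell counts equal a target count
#' table: cell probabilities are taken proportional to the target counts.
#' The table needs `band, sex, n` columns; an optional `panel` column with
#' values `TARGET_ONLY` / `TARGET_PLUS_FLAG` additionally calibrates the
#' per-cell co-medication probability of the first flag category.
#' Calibrated specs set `p_target_med = 1` and `p_lookback_only = 0` so
#' that every generated person is a medication-cohort member and the
#' expected counts are exact.
#'
#' @param target_table tibble of target counts (positive total).
#' @param n_persons population size (default: the target total).
#' @param ... further arguments passed to [population_spec()].
#' @return an `adw_population_spec`.
#' @export
calibrate_to_marginals <- function(target_table, n_persons = NULL, ...) {
  require_columns(target_table, c("band", "sex", "n"), "target_table")
  if (sum(target_table$n) <= 0) {
    stop("calibrate_to_marginals(): zero-total target table")
  }
  if (any(target_table$n < 0)) {
    stop("calibrate_to_marginals(): negative target count")
  }
  weights <- target_table |>
    group_by(.data$band, .data$sex) |>
    summarise(weight = sum(.data$n), .groups = "drop")
  flag_cell_probs <- NULL
  if ("panel" %in% names(target_table)) {
    lv <- c("TARGET_ONLY", "TARGET_PLUS_FLAG")
    if (!all(target_table$panel %in% lv)) {
      stop("calibrate_to_marginals(): panel values must be ",
           paste(lv, collapse = " / "))
    }
    flag_cell_probs <- target_table |>
      group_by(.data$band, .data$sex) |>
      summarise(
        p = sum(.data$n[.data$panel == "TARGET_PLUS_FLAG"]) / sum(.data$n),
        .groups = "drop"
      )
  }
  population_spec(
    n_persons = n_persons %||% sum(target_table$n),
    age_sex_weights = weights,
    flag_cell_probs = flag_cell_probs,
    p_target_med = 1,
    p_lookback_only = 0,
    ...
  )
}
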