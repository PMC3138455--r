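#' @title Cohort construction from linked dispensing and morbidity records
#' @description The second stage of the pipeline profiles the drug's
#'   real-world target population from person-linked administrative
#'   records: pharmaceutical dispensing claims (person, date, item code,
#'   age, sex) and hospital separations (person, date, coding system,
#'   primary plus any secondary diagnoses, age, sex). A person belongs to
#'   the target cohort for the index year when they are old enough and
#'   carry index-year evidence of the target morbidity, either a dispensing
#'   of a target-category medication or a hospital separation with a
#'   target diagnosis code in the primary *or any secondary* field.
#'   Previous-year (lookback) records supply history only and never confer
#'   membership. Members are then classified on two lattices: the
#'   medication dichotomy (target drugs only vs target plus flag-category
#'   drugs) and the merged medication/morbidity lattice.
#' @name cohort
NULL

#' Cohort-build configuration
#'
#' @param index_year calendar year defining cohort membership.
#' @param min_age minimum age in the index year (default 65).
#' @param lookback_years number of prior years whose records supply
#'   history (default 1).
#' @param high_use_threshold minimum dispensing count for a non-target,
#'   non-flag item code to be retained by [high_use_filter()]
#'   (default 3000).
#' @param target_categories code-set categories defining the target
#'   morbidity (default `c("OA", "RA")`).
#' @param flag_categories code-set categories carrying trial-excluded
#'   factors (default `c("CVD", "CVA", "RENAL")`).
#' @param bands age bands, see [default_age_bands()].
#' @param systems named list of [code_system()] objects supplying coding
#'   eras (default [default_code_systems()]).
#' @return an object of class `adw_cohort_config`.
#' @export
cohort_config <- function(index_year, min_age = 65L, lookback_years = 1L,
                          high_use_threshold = 3000L,
                          target_categories = c("OA", "RA"),
                          flag_categories = c("CVD", "CVA", "RENAL"),
                          bands = default_age_bands(),
                          systems = default_code_systems()) {
  index_year <- as.integer(index_year)
  stopifnot(length(index_year) == 1, !is.na(index_year),
            min_age >= 0, lookback_years >= 0, high_use_threshold >= 0,
            length(target_categories) >= 1)
  structure(list(
    index_year = index_year,
    min_age = as.integer(min_age),
    lookback_years = as.integer(lookback_years),
    high_use_threshold = as.integer(high_use_threshold),
    target_categories = trim_upper(target_categories),
    flag_categories = trim_upper(flag_categories),
    bands = bands,
    systems = systems
  ), class = "adw_cohort_config")
}

#' @export
print.adw_cohort_config <- function(x, ...) {
  cat("<cohort config: index year ", x$index_year, ", age >= ", x$min_age,
      ", lookback ", x$lookback_years, "y, high-use threshold ",
      fmt_n(x$high_use_threshold), ">\n",
      " target: ", paste(x$target_categories, collapse = ", "),
      "; flags: ", paste(x$flag_categories, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

new_records <- function(records, rejects, type) {
  structure(list(records = records, rejects = rejects),
            class = "adw_records", type = type)
}

#' @export
print.adw_records <- function(x, ...) {
  cat("<", attr(x, "type"), " records: ", fmt_n(nrow(x$records)),
      " valid, ", fmt_n(nrow(x$rejects)), " rejected>\n", sep = "")
  invisible(x)
}

records_of <- function(x) {
  if (inherits(x, "adw_records")) x$records else as_tibble(x)
}

validate_rows <- function(df, checks) {
  # checks: named list reason -> logical vector (TRUE = bad)
  rejects <- tibble(row = integer(0), reason = character(0),
                    data = character(0))
  bad_any <- rep(FALSE, nrow(df))
  for (reason in names(checks)) {
    bad <- checks[[reason]] & !bad_any
    if (any(bad)) {
      rejects <- bind_rows(rejects, tibble(
        row = which(bad), reason = reason,
        data = apply(df[bad, , drop = FALSE], 1, paste, collapse = ",")
      ))
    }
    bad_any <- bad_any | checks[[reason]]
  }
  list(keep = !bad_any, rejects = rejects)
}

#' Read person-level dispensing records
#'
#' Expects a CSV with columns
#' `person_id, dispense_date, item_code, age, sex` (ISO-8601 dates). Rows
#' failing validation are collected into a rejects report with the failure
#' reason, never silently dropped; a missing required column is an error.
#'
#' @param path CSV file path.
#' @return an `adw_records` object: `$records` (validated tibble) and
#'   `$rejects` (tibble `row, reason, data`).
#' @export
read_dispensing <- function(path) {
  df <- read_csv_chr(path)
  require_columns(df, c("person_id", "dispense_date", "item_code",
                        "age", "sex"), paste0("dispensing file ", path))
  df$person_id <- trimws(df$person_id)
  df$item_code <- trim_upper(df$item_code)
  df$sex <- trim_upper(df$sex)
  dates <- parse_iso_date(df$dispense_date)
  ages <- suppressWarnings(as.integer(df$age))
  v <- validate_rows(df, list(
    "empty person_id" = !nzchar(df$person_id),
    "unparseable dispense_date" = is.na(dates),
    "invalid item_code" = !grepl("^[A-Z0-9]+$", df$item_code),
    "invalid age" = is.na(ages) | ages < 0,
    "invalid sex" = !df$sex %in% c("M", "F")
  ))
  rec <- tibble(
    person_id = df$person_id[v$keep],
    dispense_date = dates[v$keep],
    item_code = df$item_code[v$keep],
    age = ages[v$keep],
    sex = df$sex[v$keep]
  )
  new_records(rec, v$rejects, "dispensing")
}

split_secondary <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(p) {
    p <- trim_upper(p)
    p[nzchar(p)]
  })
}

#' Read person-level hospital morbidity records
#'
#' Expects a CSV with columns
#' `person_id, separation_date, system, primary_dx, secondary_dx, age,
#' sex`; `secondary_dx` is a semicolon-delimited (possibly empty) list of
#' diagnosis codes and `system` is the record's coding system (`ICD9CM` or
#' `ICD10AM`). Validation failures go to the rejects report.
#'
#' @param path CSV file path.
#' @return an `adw_records` object (see [read_dispensing()]); the
#'   `secondary_dx` column of `$records` is a list-column.
#' @export
read_morbidity <- function(path) {
  df <- read_csv_chr(path)
  require_columns(df, c("person_id", "separation_date", "system",
                        "primary_dx", "secondary_dx", "age", "sex"),
                  paste0("morbidity file ", path))
  df$person_id <- trimws(df$person_id)
  df$system <- trim_upper(df$system)
  df$primary_dx <- trim_upper(df$primary_dx)
  df$sex <- trim_upper(df$sex)
  dates <- parse_iso_date(df$separation_date)
  ages <- suppressWarnings(as.integer(df$age))
  v <- validate_rows(df, list(
    "empty person_id" = !nzchar(df$person_id),
    "unparseable separation_date" = is.na(dates),
    "unknown coding system" = !df$system %in% c("ICD9CM", "ICD10AM"),
    "empty primary_dx" = !nzchar(df$primary_dx),
    "invalid age" = is.na(ages) | ages < 0,
    "invalid sex" = !df$sex %in% c("M", "F")
  ))
  rec <- tibble(
    person_id = df$person_id[v$keep],
    separation_date = dates[v$keep],
    system = df$system[v$keep],
    primary_dx = df$primary_dx[v$keep],
    secondary_dx = split_secondary(df$secondary_dx[v$keep]),
    age = ages[v$keep],
    sex = df$sex[v$keep]
  )
  new_records(rec, v$rejects, "morbidity")
}

#' Item codes always retained by the high-use filter
#'
#' The union of drug item codes in the target and flag categories; these
#' define cohort membership and flag evidence and are never dropped on
#' dispensing volume.
#'
#' @param codesets list of [code_set()] objects.
#' @param config an [cohort_config()].
#' @return character vector of item codes.
#' @export
protected_codes <- function(codesets, config) {
  codes_for(codesets,
            c(config$target_categories, config$flag_categories),
            "DRUG_ITEM")
}

#' Drop low-volume medications
#'
#' Counts dispensings per item code over the whole input and retains
#' records whose item code reaches `threshold` dispensings. Codes listed
#' in `protected` (normally [protected_codes()]: the target and flag
#' code sets) are always retained regardless of volume. The count is taken
#' across the delivered extract, i.e. the cohort-linked records as
#' supplied.
#'
#' @param dispensing dispensing records (tibble or `adw_records`).
#' @param threshold minimum dispensing count (>= 0; 0 keeps everything).
#' @param protected character vector of always-retained item codes.
#' @return list with `kept` (retained records), `dropped_item_codes`
#'   (sorted character vector) and `counts` (tibble `item_code, n, kept`).
#' @export
high_use_filter <- function(dispensing, threshold,
                            protected = character(0)) {
  stopifnot(threshold >= 0)
  d <- records_of(dispensing)
  protected <- trim_upper(protected)
  counts <- count(d, .data$item_code, name = "n")
  counts$kept <- counts$n >= threshold | counts$item_code %in% protected
  dropped <- sort(counts$item_code[!counts$kept])
  kept <- d[!d$item_code %in% dropped, , drop = FALSE]
  list(kept = kept, dropped_item_codes = dropped, counts = counts)
}

# shared evidence computation behind identify_target_cohort/build_profiles
profile_components <- function(dispensing, morbidity, codesets, config) {
  d <- records_of(dispensing)
  m <- records_of(morbidity)
  idx <- config$index_year
  lb_from <- idx - config$lookback_years

  d_year <- if (nrow(d)) year_of(d$dispense_date) else integer(0)
  m_year <- if (nrow(m)) year_of(m$separation_date) else integer(0)

  # coding-era check: flagged records are reported and excluded from
  # diagnosis evidence, never remapped
  era_ok <- rep(TRUE, nrow(m))
  for (sysn in unique(m$system)) {
    sys <- config$systems[[sysn]]
    if (is.null(sys)) next
    sel <- m$system == sysn
    era_ok[sel] <- validate_era(m$separation_date[sel], sys)
  }
  era_flagged <- m[!era_ok, , drop = FALSE]

  d_idx <- d[d_year == idx, , drop = FALSE]
  d_win <- d[d_year == idx | (d_year >= lb_from & d_year < idx), ,
             drop = FALSE]
  m_idx_all <- m[m_year == idx, , drop = FALSE]          # demographics
  m_idx <- m[m_year == idx & era_ok, , drop = FALSE]     # dx evidence

  target_items <- codes_for(codesets, config$target_categories, "DRUG_ITEM")
  med_target_ids <- unique(d_idx$person_id[d_idx$item_code %in% target_items])

  med_flag_ids <- lapply(setNames(nm = config$flag_categories), function(cat) {
    items <- codes_for(codesets, cat, "DRUG_ITEM")
    unique(d_win$person_id[d_win$item_code %in% items])
  })

  # long view of index-year diagnoses: primary OR any secondary field
  if (nrow(m_idx)) {
    n_codes <- 1L + lengths(m_idx$secondary_dx)
    dx_long <- tibble(
      person_id = rep(m_idx$person_id, times = n_codes),
      system = rep(m_idx$system, times = n_codes),
      code = unlist(Map(c, m_idx$primary_dx, m_idx$secondary_dx),
                    use.names = FALSE)
    )
  } else {
    dx_long <- tibble(person_id = character(0), system = character(0),
                      code = character(0))
  }
  match_cat_ids <- function(cat) {
    hit <- rep(FALSE, nrow(dx_long))
    for (sysn in unique(dx_long$system)) {
      set <- merged_set_for(codesets, cat, sysn)
      if (is.null(set)) next
      sel <- dx_long$system == sysn
      hit[sel] <- hit[sel] | match_code(dx_long$code[sel], set)
    }
    unique(dx_long$person_id[hit])
  }
  dx_target_ids <- unique(unlist(lapply(config$target_categories,
                                        match_cat_ids), use.names = FALSE))
  dx_flag_ids <- lapply(setNames(nm = config$flag_categories), match_cat_ids)

  # demographics from index-year records; age is the max recorded age
  demo <- bind_rows(
    if (nrow(d_idx)) tibble(person_id = d_idx$person_id, age = d_idx$age,
                            sex = d_idx$sex),
    if (nrow(m_idx_all)) tibble(person_id = m_idx_all$person_id,
                                age = m_idx_all$age, sex = m_idx_all$sex)
  )
  # sex from all records (any year), majority value, ties to first sorted
  sex_all <- bind_rows(
    if (nrow(d)) tibble(person_id = d$person_id, sex = d$sex),
    if (nrow(m)) tibble(person_id = m$person_id, sex = m$sex)
  )

  list(
    era_flagged = era_flagged,
    med_target_ids = med_target_ids,
    med_flag_ids = med_flag_ids,
    dx_target_ids = dx_target_ids %||% character(0),
    dx_flag_ids = dx_flag_ids,
    hospital_ids = unique(m_idx$person_id),
    demo = demo,
    sex_all = sex_all
  )
}

#' Identify the target-morbidity cohort
#'
#' A person is a member iff their index-year age reaches `min_age` and
#' they have index-year target evidence: a dispensing of a target-category
#' medication, or a hospital separation carrying a target diagnosis code
#' in the primary or any secondary field. Lookback-year records never
#' confer membership.
#'
#' @param dispensing,morbidity records (tibbles or `adw_records`).
#' @param codesets list of [code_set()] objects covering the configured
#'   categories.
#' @param config an [cohort_config()].
#' @return sorted character vector of member person ids.
#' @export
identify_target_cohort <- function(dispensing, morbidity, codesets, config) {
  pc <- profile_components(dispensing, morbidity, codesets, config)
  candidates <- union(pc$med_target_ids, pc$dx_target_ids)
  if (length(candidates) == 0) return(character(0))
  ages <- pc$demo |>
    filter(.data$person_id %in% candidates) |>
    group_by(.data$person_id) |>
    summarise(age = max(.data$age), .groups = "drop")
  sort(ages$person_id[ages$age >= config$min_age])
}

#' Build per-person profiles for the merged cohort
#'
#' Produces one row per cohort member with their age band, sex,
#' target-evidence booleans, any-hospital-record boolean and one
#' medication flag (`med_<CAT>`, index-year or lookback dispensing) and
#' one diagnosis flag (`dx_<CAT>`, index-year valid separation) per flag
#' category. Persons with contradictory sex across records keep the
#' majority value and are flagged in `sex_conflict`. Era-flagged morbidity
#' records are excluded from diagnosis evidence and reported in the
#' `era_flagged` attribute.
#'
#' @inheritParams identify_target_cohort
#' @return an `adw_profiles` tibble (one row per member) with attributes
#'   `config` and `era_flagged`.
#' @export
build_profiles <- function(dispensing, morbidity, codesets, config) {
  pc <- profile_components(dispensing, morbidity, codesets, config)
  members <- identify_target_cohort(dispensing, morbidity, codesets, config)

  if (length(members)) {
    ages <- pc$demo |>
      filter(.data$person_id %in% members) |>
      group_by(.data$person_id) |>
      summarise(age = max(.data$age), .groups = "drop")
    sex_tab <- pc$sex_all |>
      filter(.data$person_id %in% members) |>
      count(.data$person_id, .data$sex) |>
      group_by(.data$person_id) |>
      summarise(
        sex_conflict = n_distinct(.data$sex) > 1,
        sex = .data$sex[order(-.data$n, .data$sex)][1],
        .groups = "drop"
      ) |>
      relocate("sex", .before = "sex_conflict")
    if (any(sex_tab$sex_conflict)) {
      message(sum(sex_tab$sex_conflict),
              " person(s) with contradictory sex across records; ",
              "majority value retained")
    }
    prof <- tibble(person_id = members) |>
      left_join(ages, by = "person_id") |>
      left_join(sex_tab, by = "person_id") |>
      mutate(
        age_band = age_band(.data$age, config$bands),
        has_target_med = .data$person_id %in% pc$med_target_ids,
        has_target_dx = .data$person_id %in% pc$dx_target_ids,
        has_hospital_dx = .data$person_id %in% pc$hospital_ids
      ) |>
      relocate("age_band", .after = "age")
    for (cat in config$flag_categories) {
      prof[[paste0("med_", cat)]] <- prof$person_id %in% pc$med_flag_ids[[cat]]
      prof[[paste0("dx_", cat)]] <- prof$person_id %in% pc$dx_flag_ids[[cat]]
    }
  } else {
    prof <- tibble(
      person_id = character(0), age = integer(0), age_band = character(0),
      sex = character(0), sex_conflict = logical(0),
      has_target_med = logical(0), has_target_dx = logical(0),
      has_hospital_dx = logical(0)
    )
    for (cat in config$flag_categories) {
      prof[[paste0("med_", cat)]] <- logical(0)
      prof[[paste0("dx_", cat)]] <- logical(0)
    }
  }
  structure(prof, class = c("adw_profiles", class(prof)),
            config = config, era_flagged = pc$era_flagged)
}

#' Medication dichotomy: target drugs only vs target plus flag drugs
#'
#' Classifies target-medicated members as `TARGET_PLUS_FLAG` when at least
#' one flag-category medication flag is set (dispensing evidence in the
#' index year or lookback), else `TARGET_ONLY`. Diagnosis-based flags play
#' no part in this dichotomy; they enter through the merged lattice and
#' the cross-tab stage. Calling this on profiles without target
#' medication is an error: filter on `has_target_med` first.
#'
#' @param profiles an `adw_profiles` tibble, all rows with
#'   `has_target_med` `TRUE`.
#' @return factor with levels `TARGET_ONLY`, `TARGET_PLUS_FLAG`.
#' @export
classify_patient <- function(profiles) {
  if (nrow(profiles) && !all(profiles$has_target_med)) {
    stop("classify_patient() requires profiles with target medication; ",
         "filter on has_target_med first")
  }
  med_cols <- grep("^med_", names(profiles), value = TRUE)
  any_flag <- if (length(med_cols)) {
    rowSums(as.matrix(profiles[med_cols])) > 0
  } else {
    rep(FALSE, nrow(profiles))
  }
  factor(ifelse(any_flag, "TARGET_PLUS_FLAG", "TARGET_ONLY"),
         levels = c("TARGET_ONLY", "TARGET_PLUS_FLAG"))
}

#' Merged medication/morbidity lattice
#'
#' Partitions the merged cohort (medication members plus
#' hospital-diagnosed members) into four mutually exclusive, exhaustive
#' classes with the precedence: target medication and a target diagnosis
#' gives `MEDS_AND_TARGET_DX`; target medication with only non-target
#' hospital diagnoses gives `MEDS_AND_NONTARGET_DX`; target medication and
#' no hospital record gives `MEDS_ONLY`; a target diagnosis without target
#' medication gives `DX_ONLY`.
#'
#' @param profiles an `adw_profiles` tibble over the merged cohort.
#' @return factor with levels `MEDS_ONLY`, `DX_ONLY`,
#'   `MEDS_AND_TARGET_DX`, `MEDS_AND_NONTARGET_DX`.
#' @export
merge_profiles <- function(profiles) {
  med <- profiles$has_target_med
  tdx <- profiles$has_target_dx
  hosp <- profiles$has_hospital_dx
  if (any(!med & !tdx)) {
    stop("internal error: profile without target medication or target ",
         "diagnosis reached merge_profiles()")
  }
  cls <- ifelse(med & tdx, "MEDS_AND_TARGET_DX",
         ifelse(med & hosp, "MEDS_AND_NONTARGET_DX",
         ifelse(med, "MEDS_ONLY", "DX_ONLY")))
  factor(cls, levels = c("MEDS_ONLY", "DX_ONLY", "MEDS_AND_TARGET_DX",
                         "MEDS_AND_NONTARGET_DX"))
}

#' Re-read a profiles CSV written by [write_profiles()]
#'
#' @param path CSV file path.
#' @return a tibble with logical evidence/flag columns restored.
#' @export
read_profiles <- function(path) {
  df <- read_csv_chr(path)
  require_columns(df, c("person_id", "age", "age_band", "sex",
                        "has_target_med", "has_target_dx",
                        "has_hospital_dx"), paste0("profiles file ", path))
  df <- as_tibble(df)
  df$age <- as.integer(df$age)
  lg <- grep("^(has_|med_|dx_)|^sex_conflict$", names(df), value = TRUE)
  for (col in lg) df[[col]] <- toupper(df[[col]]) == "TRUE"
  df
}

#' Write profiles to CSV
#'
#' @param profiles an `adw_profiles` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  write.csv(as.data.frame(profiles), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
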