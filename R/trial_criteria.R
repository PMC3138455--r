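#' @title Structured clinical-trial exclusion criteria
#' @description The first stage of the pipeline is a reading exercise: the
#'   exclusion protocols of a new drug's pre-release trials are curated by
#'   hand into a criteria file, one row per criterion, with trial metadata
#'   repeated per row. This module parses that file, distinguishes
#'   exclusions that enable the trial's own research question
#'   (`QUESTION_SPECIFIC`, e.g. gastric morbidity exclusions in a
#'   gastric-safety trial) from exclusions relating to other body systems
#'   (`OTHER_SYSTEM`, e.g. cardiovascular exclusions in an arthritis
#'   efficacy trial), and aggregates criteria across trials into a
#'   per-indication exclusion profile.
#' @name trial_criteria
NULL

CRITERION_DOMAINS <- c("COMORBIDITY", "CO_MEDICATION", "DEMOGRAPHIC")
TRIAL_TYPES <- c("EFFICACY", "SAFETY", "POOLED")
RELEVANCE_LEVELS <- c("QUESTION_SPECIFIC", "OTHER_SYSTEM")

#' Parse a trial exclusion-criteria file
#'
#' The file is a CSV with columns
#' `trial_id, indication, trial_type, domain, category, body_system,
#' time_window_years, description`, one row per criterion. A row whose
#' `domain` and `category` are both empty declares a trial with no
#' criteria. `DEMOGRAPHIC` criteria carry an age/sex bound in `category`
#' and are never resolved against code sets; other criteria must name a
#' category present in `categories` when that argument is supplied.
#'
#' @param path criteria CSV path.
#' @param categories optional character vector of known code-set category
#'   labels used to validate criterion bindings (e.g.
#'   `codeset_categories(example_codesets())`).
#' @return an object of class `adw_trial_criteria`: a list with
#'   `$trials` (tibble `trial_id, indication, trial_type`) and `$criteria`
#'   (tibble of criterion rows keyed by `trial_id`).
#' @export
parse_criteria_file <- function(path, categories = NULL) {
  df <- read_csv_chr(path)
  cols <- c("trial_id", "indication", "trial_type", "domain", "category",
            "body_system", "time_window_years", "description")
  require_columns(df, cols, paste0("criteria file ", path))
  if (nrow(df) == 0) stop("criteria file ", path, " has no rows")

  df$trial_id <- trimws(df$trial_id)
  df$indication <- trim_upper(df$indication)
  df$trial_type <- trim_upper(df$trial_type)
  df$domain <- trim_upper(df$domain)
  df$category <- trim_upper(df$category)
  df$body_system <- tolower(trimws(df$body_system))
  df$description <- trimws(df$description)

  if (any(!nzchar(df$trial_id))) {
    stop("criteria file: empty trial_id at row(s) ",
         paste(which(!nzchar(df$trial_id)), collapse = ", "))
  }
  if (any(!nzchar(df$indication))) {
    stop("criteria file: empty indication at row(s) ",
         paste(which(!nzchar(df$indication)), collapse = ", "))
  }
  bad_type <- which(!df$trial_type %in% TRIAL_TYPES)
  if (length(bad_type) > 0) {
    stop("criteria file: unknown trial_type at row(s) ",
         paste(bad_type, collapse = ", "), ": ",
         paste(unique(df$trial_type[bad_type]), collapse = ", "))
  }

  trials <- distinct(as_tibble(df[c("trial_id", "indication", "trial_type")]))
  if (anyDuplicated(trials$trial_id)) {
    stop("criteria file: trial_id(s) with conflicting metadata: ",
         paste(unique(trials$trial_id[duplicated(trials$trial_id)]),
               collapse = ", "))
  }

  is_decl <- !nzchar(df$domain) & !nzchar(df$category)
  crit <- df[!is_decl, , drop = FALSE]
  rows <- which(!is_decl)

  bad_dom <- which(!crit$domain %in% CRITERION_DOMAINS)
  if (length(bad_dom) > 0) {
    stop("criteria file: unknown domain token at row(s) ",
         paste(rows[bad_dom], collapse = ", "), " (trial ",
         paste(unique(crit$trial_id[bad_dom]), collapse = ", "), "): ",
         paste(unique(crit$domain[bad_dom]), collapse = ", "))
  }
  no_sys <- which(!nzchar(crit$body_system))
  if (length(no_sys) > 0) {
    stop("criteria file: missing body_system tag at row(s) ",
         paste(rows[no_sys], collapse = ", "),
         " (the tag is required for every criterion)")
  }
  if (!is.null(categories)) {
    categories <- trim_upper(categories)
    needs <- crit$domain != "DEMOGRAPHIC"
    unknown <- which(needs & !crit$category %in% categories)
    if (length(unknown) > 0) {
      stop("criteria file: category not in the code-set manifest at row(s) ",
           paste(rows[unknown], collapse = ", "), " (trial ",
           paste(unique(crit$trial_id[unknown]), collapse = ", "), "): ",
           paste(unique(crit$category[unknown]), collapse = ", "))
    }
  }

  tw <- suppressWarnings(as.numeric(crit$time_window_years))
  bad_tw <- which(nzchar(trimws(crit$time_window_years)) & is.na(tw))
  if (length(bad_tw) > 0) {
    stop("criteria file: non-numeric time_window_years at row(s) ",
         paste(rows[bad_tw], collapse = ", "))
  }
  if (any(!is.na(tw) & tw <= 0)) {
    stop("criteria file: time_window_years must be positive when present")
  }

  criteria <- as_tibble(crit[c("trial_id", "indication", "trial_type",
                               "domain", "category", "body_system",
                               "description")])
  criteria$time_window_years <- tw
  structure(list(trials = trials, criteria = criteria),
            class = "adw_trial_criteria")
}

#' @export
print.adw_trial_criteria <- function(x, ...) {
  cat("<trial criteria: ", nrow(x$trials), " trial(s), ",
      nrow(x$criteria), " criterion row(s)>\n", sep = "")
  print(count(x$trials, .data$indication, .data$trial_type))
  invisible(x)
}

#' Classify criteria as question-specific or other-system
#'
#' A criterion whose `body_system` tag names one of the body systems tied
#' to the trials' own research questions is `QUESTION_SPECIFIC` (a
#' legitimate design control); all other criteria are `OTHER_SYSTEM` and
#' are the ones that remove evidence about the drug's action in patients
#' carrying those factors. Only `OTHER_SYSTEM` criteria feed the
#' discordance stage by default.
#'
#' @param criteria a criteria tibble (the `$criteria` component of
#'   [parse_criteria_file()]) or an `adw_trial_criteria` object.
#' @param target_systems character vector of body-system labels addressed
#'   by the drug's research questions (e.g. `"musculoskeletal"` for an
#'   arthritis efficacy question, `"gastrointestinal"` for a
#'   gastric-safety question).
#' @return character vector over criterion rows with values
#'   `"QUESTION_SPECIFIC"` / `"OTHER_SYSTEM"`.
#' @export
classify_relevance <- function(criteria, target_systems) {
  if (inherits(criteria, "adw_trial_criteria")) criteria <- criteria$criteria
  stopifnot(is.character(target_systems), length(target_systems) >= 1)
  target_systems <- tolower(trimws(target_systems))
  bs <- criteria$body_system
  if (is.null(bs) || any(is.na(bs) | !nzchar(bs))) {
    stop("classify_relevance(): criterion without a body_system tag")
  }
  ifelse(tolower(bs) %in% target_systems,
         "QUESTION_SPECIFIC", "OTHER_SYSTEM")
}

#' Aggregate trial exclusion criteria into an exclusion profile
#'
#' Takes the union of criteria over all trials matching `indication`, one
#' profile entry per `(domain, category)` pair. Each entry records every
#' supporting trial, the tightest (smallest) time window when windows
#' differ across trials (with the range noted), and its relevance
#' classification. `QUESTION_SPECIFIC` entries are retained in the profile
#' but excluded from discordance scoring by default (see
#' [compare_profiles()]).
#'
#' @param x an `adw_trial_criteria` object (or its `$criteria` tibble).
#' @param indication indication label to aggregate over (e.g. `"OA"`).
#' @param target_systems passed to [classify_relevance()].
#' @param drug drug name recorded on the profile.
#' @return an object of class `adw_exclusion_profile`: a tibble with one
#'   row per entry (`domain, category, relevance, description, trial_ids,
#'   n_trials, time_window_years, window_range`) and attributes `drug`,
#'   `indication`, `target_systems`.
#' @export
aggregate_exclusions <- function(x, indication, target_systems,
                                 drug = "unspecified drug") {
  criteria <- if (inherits(x, "adw_trial_criteria")) x$criteria else x
  indication <- trim_upper(indication)
  crit <- filter(criteria, .data$indication == !!indication)
  if (nrow(crit) > 0) {
    crit$relevance <- classify_relevance(crit, target_systems)
    entries <- crit |>
      group_by(.data$domain, .data$category) |>
      summarise(
        relevance = if (any(.data$relevance == "OTHER_SYSTEM"))
          "OTHER_SYSTEM" else "QUESTION_SPECIFIC",
        description = paste(unique(.data$description[nzchar(.data$description)]),
                            collapse = "; "),
        trial_ids = list(sort(unique(.data$trial_id))),
        n_trials = length(unique(.data$trial_id)),
        window_range = {
          w <- sort(unique(.data$time_window_years[!is.na(.data$time_window_years)]))
          if (length(w) > 1) {
            paste0("windows vary across trials: ",
                   paste(w, collapse = ", "), " years")
          } else NA_character_
        },
        time_window_years = if (all(is.na(.data$time_window_years)))
          NA_real_ else min(.data$time_window_years, na.rm = TRUE),
        .groups = "drop"
      ) |>
      relocate("window_range", .after = "time_window_years") |>
      arrange(.data$domain, .data$category)
  } else {
    entries <- tibble(
      domain = character(0), category = character(0),
      relevance = character(0), description = character(0),
      trial_ids = list(), n_trials = integer(0),
      time_window_years = numeric(0), window_range = character(0)
    )
  }
  structure(entries,
            class = c("adw_exclusion_profile", class(entries)),
            drug = drug, indication = indication,
            target_systems = tolower(trimws(target_systems)))
}

#' @export
print.adw_exclusion_profile <- function(x, ...) {
  cat("<exclusion profile: ", attr(x, "drug"), ", indication ",
      attr(x, "indication"), ", ", nrow(x), " entr",
      if (nrow(x) == 1) "y" else "ies", ">\n", sep = "")
  NextMethod()
  invisible(x)
}
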