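#' @title Trial-exclusion vs real-world discordance
#' @description The third stage compares the structured trial exclusion
#'   profile with the real-world cohort profile. Every other-body-system
#'   exclusion category becomes a discordance entry carrying its
#'   real-world carrier count and prevalence; entries whose prevalence
#'   reaches a configurable threshold are flagged, and the result is
#'   rendered as a prescriber risk advisory. The advisory asserts the
#'   *absence of trial evidence* about the drug's action in those patient
#'   groups, not the presence of harm.
#' @name discordance
NULL

DOMAIN_ORDER <- c("COMORBIDITY", "CO_MEDICATION", "DEMOGRAPHIC")

#' Compare an exclusion profile with the cohort profile
#'
#' One discordance entry is produced per exclusion-profile entry
#' (`(domain, category)` pair). Prevalence denominators follow the
#' evidence: medication evidence is counted among the target-medication
#' cohort, diagnosis evidence over the whole merged cohort; each entry
#' states its denominator. `CO_MEDICATION` entries use medication evidence
#' as primary, `COMORBIDITY` entries diagnosis evidence; when the other
#' evidence stream also exists for the category it is reported as
#' secondary (the two streams have different denominators and are never
#' pooled). Categories with no computable evidence (no flag columns in the
#' profiles — e.g. an excluded morbidity for which no code set was
#' extracted) and `DEMOGRAPHIC` entries surface as "insufficient data"
#' entries rather than being dropped. An entry is flagged iff its primary
#' prevalence reaches `threshold`.
#'
#' @param exclusion an [aggregate_exclusions()] profile.
#' @param profiles an `adw_profiles` tibble over the merged cohort (must
#'   be non-empty).
#' @param threshold flag threshold, percentage points (default 10).
#' @param include_question_specific also score `QUESTION_SPECIFIC`
#'   entries (default `FALSE`: they are legitimate design controls).
#' @param config the [cohort_config()] describing the cohort (taken from
#'   the profiles' attribute when present; used for the advisory's cohort
#'   descriptor only).
#' @return an object of class `adw_risk_advisory`.
#' @export
compare_profiles <- function(exclusion, profiles, threshold = 10,
                             include_question_specific = FALSE,
                             config = attr(profiles, "config")) {
  stopifnot(inherits(exclusion, "adw_exclusion_profile"))
  if (nrow(profiles) == 0) {
    stop("compare_profiles(): empty cohort")
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1, threshold >= 0)

  entries <- as_tibble(exclusion)
  if (!include_question_specific && nrow(entries) > 0) {
    entries <- filter(entries, .data$relevance == "OTHER_SYSTEM")
  }
  n_merged <- nrow(profiles)
  n_med <- sum(profiles$has_target_med)

  score_one <- function(i) {
    cat <- entries$category[i]
    dom <- entries$domain[i]
    med_col <- paste0("med_", cat)
    dx_col <- paste0("dx_", cat)
    med_ev <- if (med_col %in% names(profiles) && n_med > 0) {
      list(source = "medication",
           count = sum(profiles[[med_col]] & profiles$has_target_med),
           denominator = n_med)
    }
    dx_ev <- if (dx_col %in% names(profiles)) {
      list(source = "diagnosis",
           count = sum(profiles[[dx_col]]),
           denominator = n_merged)
    }
    ev <- switch(dom,
      CO_MEDICATION = list(primary = med_ev, secondary = dx_ev),
      COMORBIDITY = list(primary = dx_ev, secondary = med_ev),
      DEMOGRAPHIC = list(primary = NULL, secondary = NULL)
    )
    p <- ev$primary
    s <- ev$secondary
    tibble(
      category = cat,
      domain = dom,
      relevance = entries$relevance[i],
      trial_ids = list(entries$trial_ids[[i]]),
      n_trials = entries$n_trials[i],
      time_window_years = entries$time_window_years[i],
      evidence_source = if (is.null(p)) NA_character_ else p$source,
      cohort_count = if (is.null(p)) NA_integer_ else as.integer(p$count),
      denominator = if (is.null(p)) NA_integer_ else as.integer(p$denominator),
      cohort_prevalence = if (is.null(p)) NA_real_ else
        prevalence(p$count, p$denominator, 1),
      secondary_source = if (is.null(s)) NA_character_ else s$source,
      secondary_count = if (is.null(s)) NA_integer_ else as.integer(s$count),
      secondary_denominator = if (is.null(s)) NA_integer_ else
        as.integer(s$denominator),
      secondary_prevalence = if (is.null(s)) NA_real_ else
        prevalence(s$count, s$denominator, 1),
      note = if (is.null(p)) "insufficient data: no cohort evidence computed"
        else NA_character_
    )
  }
  scored <- if (nrow(entries) > 0) {
    bind_rows(lapply(seq_len(nrow(entries)), score_one))
  } else {
    tibble(
      category = character(0), domain = character(0),
      relevance = character(0), trial_ids = list(),
      n_trials = integer(0), time_window_years = numeric(0),
      evidence_source = character(0), cohort_count = integer(0),
      denominator = integer(0), cohort_prevalence = numeric(0),
      secondary_source = character(0), secondary_count = integer(0),
      secondary_denominator = integer(0), secondary_prevalence = numeric(0),
      note = character(0)
    )
  }
  scored$flagged <- !is.na(scored$cohort_prevalence) &
    scored$cohort_prevalence >= threshold
  scored <- rank_entries(scored)

  structure(list(
    drug = attr(exclusion, "drug"),
    indication = attr(exclusion, "indication"),
    threshold = threshold,
    cohort = list(
      index_year = config$index_year %||% NA_integer_,
      min_age = config$min_age %||% NA_integer_,
      n_merged = n_merged,
      n_medication = n_med
    ),
    entries = scored
  ), class = "adw_risk_advisory")
}

#' Rank discordance entries
#'
#' Descending by prevalence (entries without a computable prevalence
#' last); ties broken by domain order `COMORBIDITY < CO_MEDICATION <
#' DEMOGRAPHIC`, then category label.
#'
#' @param entries a discordance-entry tibble with `cohort_prevalence`,
#'   `domain` and `category` columns.
#' @return the tibble, reordered.
#' @export
rank_entries <- function(entries) {
  if (nrow(entries) == 0) return(entries)
  p <- entries$cohort_prevalence
  ord <- order(is.na(p), -ifelse(is.na(p), 0, p),
               match(entries$domain, DOMAIN_ORDER), entries$category)
  entries[ord, , drop = FALSE]
}

#' @export
print.adw_risk_advisory <- function(x, ...) {
  cat(render_advisory(x, format = "text"))
  invisible(x)
}

#' Render a risk advisory
#'
#' The text form is the prescriber-facing advisory: it names the drug and
#' indication, describes the cohort, lists every flagged excluded factor
#' with its carrier count, prevalence, denominator and supporting trials,
#' notes unflagged and insufficient-data entries, and closes with the
#' monitoring caution. The structured form is a plain list with identical
#' content, suitable for [jsonlite::toJSON()]. Rendering is deterministic:
#' the same advisory always yields identical output.
#'
#' @param advisory an `adw_risk_advisory`.
#' @param format `"text"` or `"structured"`.
#' @return a single string (`"text"`) or a list (`"structured"`).
#' @export
render_advisory <- function(advisory, format = c("text", "structured")) {
  stopifnot(inherits(advisory, "adw_risk_advisory"))
  format <- match.arg(format)
  e <- advisory$entries
  co <- advisory$cohort

  if (format == "structured") {
    ent <- lapply(seq_len(nrow(e)), function(i) {
      r <- as.list(e[i, setdiff(names(e), "trial_ids")])
      r$trial_ids <- e$trial_ids[[i]]
      r
    })
    return(list(
      drug = advisory$drug,
      indication = advisory$indication,
      flag_threshold_pct = advisory$threshold,
      cohort = co,
      entries = ent
    ))
  }

  hdr <- c(
    paste0("RISK ADVISORY: ", advisory$drug, " (indication: ",
           advisory$indication, ")"),
    paste0("Cohort: persons aged >= ", co$min_age,
           " with target-morbidity evidence in ", co$index_year,
           "; merged cohort n = ", fmt_n(co$n_merged),
           " (", fmt_n(co$n_medication), " on target medication)"),
    paste0("Flag threshold: prevalence >= ", advisory$threshold, "%"),
    ""
  )
  if (nrow(e) == 0) {
    body <- paste0("No other-body-system exclusion criteria were ",
                   "identified in the analysed trials; no patient groups ",
                   "are flagged.")
    return(paste0(paste(c(hdr, body), collapse = "\n"), "\n"))
  }
  line_for <- function(i) {
    r <- e[i, ]
    base <- paste0(r$category, " [", r$domain, "]")
    if (is.na(r$cohort_prevalence)) {
      paste0("  - ", base, ": insufficient data (no cohort evidence ",
             "computed); excluded in ", r$n_trials, " trial(s): ",
             paste(e$trial_ids[[i]], collapse = ", "))
    } else {
      paste0("  - ", base, ": ", fmt_n(r$cohort_count), " of ",
             fmt_n(r$denominator), " patients (",
             formatC(r$cohort_prevalence, format = "f", digits = 1),
             "%, ", r$evidence_source, " evidence); excluded in ",
             r$n_trials, " trial(s): ",
             paste(e$trial_ids[[i]], collapse = ", "),
             if (!is.na(r$secondary_prevalence)) {
               paste0(" [also ",
                      formatC(r$secondary_prevalence, format = "f",
                              digits = 1),
                      "% by ", r$secondary_source, " evidence, n = ",
                      fmt_n(r$secondary_denominator), "]")
             } else "")
    }
  }
  flagged <- which(e$flagged)
  rest <- which(!e$flagged)
  body <- c(
    if (length(flagged)) c("FLAGGED patient groups (trial-excluded factors prevalent in the real-world cohort):",
                           vapply(flagged, line_for, character(1)))
    else "No entry reached the flag threshold.",
    if (length(rest)) c("", "Other excluded factors (below threshold or insufficient data):",
                        vapply(rest, line_for, character(1))),
    "",
    paste0("Caution: the analysed trials provide little or no evidence on ",
           "the action of ", advisory$drug, " in patients carrying the ",
           "factors above. If ", advisory$drug, " is prescribed to such ",
           "patients, monitor them closely.")
  )
  paste0(paste(c(hdr, body), collapse = "\n"), "\n")
}
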