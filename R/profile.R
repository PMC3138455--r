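#' @title Age-band by sex cross-tabulations
#' @description Classified patient profiles are summarised the way
#'   drug-utilisation studies print them: counts by five-year age band and
#'   sex for one or more panels (predicates over profiles), with derived
#'   row percentages, male:female ratios, per-(sex, panel) subtotals and
#'   grand totals. All percentages use half-up rounding and the female
#'   share of a ratio is defined as the complement of the rounded male
#'   share, so printed ratio pairs always sum to 100.
#' @name profile_tables
NULL

#' Default age bands
#'
#' Five bands from 65 to 99; the top band is open-ended in effect (older
#' ages clamp into it with a logged note).
#'
#' @return tibble with columns `label, lower, upper`.
#' @export
default_age_bands <- function() {
  tibble(
    label = c("65-69", "70-74", "75-79", "80-84", "85-99"),
    lower = c(65L, 70L, 75L, 80L, 85L),
    upper = c(69L, 74L, 79L, 84L, 99L)
  )
}

#' Assign ages to age bands
#'
#' Ages above the top band's upper bound map to the top band with a note;
#' ages below the lowest band are an error (the cohort age gate should
#' have removed them).
#'
#' @param age integer vector of ages.
#' @param bands band definition, see [default_age_bands()].
#' @return character vector of band labels.
#' @examples
#' age_band(c(67, 99))  # "65-69" "85-99"
#' @export
age_band <- function(age, bands = default_age_bands()) {
  stopifnot(all(diff(bands$lower) > 0), all(bands$lower <= bands$upper))
  if (any(age < min(bands$lower))) {
    stop("age_band(): age(s) below the lowest band: ",
         paste(sort(unique(age[age < min(bands$lower)])), collapse = ", "))
  }
  top <- max(bands$upper)
  if (any(age > top)) {
    message(sum(age > top), " age(s) above ", top,
            " clamped into the top band")
  }
  idx <- findInterval(pmin(age, top), bands$lower)
  bands$label[idx]
}

#' Cross-tabulate profiles by age band, sex and panel
#'
#' Each panel is a named predicate over the profiles tibble (a function
#' returning one logical per row). Panels are not forced to be disjoint: a
#' profile may satisfy several (overlap counts are reported separately in
#' practice). With `strict = TRUE` an error is raised if any profile
#' satisfies more than one panel.
#'
#' @param profiles a profiles tibble with `age_band` and `sex` columns.
#' @param panels named list of predicate functions.
#' @param bands band definition used for row ordering.
#' @param strict require panels to be disjoint.
#' @return an object of class `adw_crosstab` with `$cells` (tibble
#'   `band, sex, panel, n` over the complete grid).
#' @export
cross_tab <- function(profiles, panels, bands = default_age_bands(),
                      strict = FALSE) {
  stopifnot(is.list(panels), length(panels) >= 1,
            !is.null(names(panels)), all(nzchar(names(panels))))
  hits <- lapply(panels, function(f) {
    h <- f(profiles)
    stopifnot(is.logical(h), length(h) == nrow(profiles))
    h & !is.na(h)
  })
  if (strict && nrow(profiles) > 0) {
    overlap <- Reduce(`+`, hits) > 1
    if (any(overlap)) {
      stop("cross_tab(strict = TRUE): ", sum(overlap),
           " profile(s) satisfy more than one panel")
    }
  }
  grid <- tidyr::expand_grid(band = bands$label, sex = c("M", "F"),
                             panel = names(panels))
  counted <- bind_rows(lapply(names(panels), function(pn) {
    sel <- profiles[hits[[pn]], , drop = FALSE]
    if (nrow(sel) == 0) {
      return(tibble(band = character(0), sex = character(0),
                    panel = character(0), n = integer(0)))
    }
    cnt <- count(sel, band = .data$age_band, sex = .data$sex, name = "n")
    cnt$panel <- pn
    cnt
  }))
  cells <- grid |>
    left_join(counted, by = c("band", "sex", "panel")) |>
    mutate(n = coalesce(as.integer(.data$n), 0L))
  structure(list(cells = cells, bands = bands, panels = names(panels),
                 n_profiles = nrow(profiles)),
            class = "adw_crosstab")
}

#' @export
print.adw_crosstab <- function(x, ...) {
  cat("<cross-tab: ", length(x$panels), " panel(s) x ",
      nrow(x$bands), " band(s) x sex>\n", sep = "")
  wide <- tidyr::pivot_wider(x$cells, names_from = c("panel", "sex"),
                             values_from = "n")
  print(wide)
  st <- xtab_subtotals(x)
  cat("subtotals:\n")
  print(st)
  invisible(x)
}

#' Per-(panel, sex) subtotals of a cross-tab
#'
#' @param x an `adw_crosstab`.
#' @return tibble `panel, sex, n`.
#' @export
xtab_subtotals <- function(x) {
  stopifnot(inherits(x, "adw_crosstab"))
  x$cells |>
    group_by(.data$panel, .data$sex) |>
    summarise(n = sum(.data$n), .groups = "drop")
}

#' Per-panel totals of a cross-tab
#'
#' @param x an `adw_crosstab`.
#' @return tibble `panel, n`.
#' @export
xtab_panel_totals <- function(x) {
  stopifnot(inherits(x, "adw_crosstab"))
  x$cells |>
    group_by(.data$panel) |>
    summarise(n = sum(.data$n), .groups = "drop")
}

#' Row shares across panels
#'
#' For each age band, the percentage of the row total (summed over sexes
#' and panels) falling in each panel — the form of a medication-dichotomy
#' table's row percentages. Meaningful when the panels partition the
#' profiles.
#'
#' @param x an `adw_crosstab`.
#' @param decimals decimal places for the percentage.
#' @return tibble `band, panel, n, pct`.
#' @export
xtab_row_share <- function(x, decimals = 0) {
  stopifnot(inherits(x, "adw_crosstab"))
  by_band <- x$cells |>
    group_by(.data$band, .data$panel) |>
    summarise(n = sum(.data$n), .groups = "drop_last") |>
    mutate(row_total = sum(.data$n)) |>
    ungroup()
  by_band$pct <- ifelse(by_band$row_total > 0,
                        prevalence(by_band$n, pmax(by_band$row_total, 1),
                                   decimals),
                        NA_real_)
  select(by_band, "band", "panel", "n", "pct")
}

#' Male:female split per band and panel
#'
#' @param x an `adw_crosstab`.
#' @return tibble `band, panel, male_n, female_n, male_pct, female_pct`;
#'   percentage pairs are `NA` for empty cells pairs.
#' @export
xtab_sex_split <- function(x) {
  stopifnot(inherits(x, "adw_crosstab"))
  wide <- x$cells |>
    tidyr::pivot_wider(names_from = "sex", values_from = "n") |>
    rename(male_n = "M", female_n = "F")
  nonzero <- wide$male_n + wide$female_n > 0
  wide$male_pct <- NA_real_
  wide$female_pct <- NA_real_
  if (any(nonzero)) {
    sr <- sex_ratio(wide$male_n[nonzero], wide$female_n[nonzero])
    wide$male_pct[nonzero] <- sr$male
    wide$female_pct[nonzero] <- sr$female
  }
  select(wide, "band", "panel", "male_n", "female_n", "male_pct",
         "female_pct")
}

#' Percentage prevalence with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places.
#'
#' @param numerator,denominator non-negative counts,
#'   `numerator <= denominator`, `denominator > 0`.
#' @param decimals decimal places (default 1).
#' @return numeric vector of percentages.
#' @examples
#' prevalence(40595, 58968, 1)  # 68.8
#' @export
prevalence <- function(numerator, denominator, decimals = 1) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) stop("prevalence(): denominator must be > 0")
  if (any(numerator < 0)) stop("prevalence(): negative numerator")
  if (any(numerator > denominator)) {
    stop("prevalence(): numerator exceeds denominator")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

#' Male and female percentage shares
#'
#' The male share is rounded half-up to an integer; the female share is
#' defined as its complement (`100 - male`), so every pair sums to 100.
#'
#' @param male_count,female_count non-negative counts with
#'   `male_count + female_count > 0` pairwise.
#' @return tibble with integer columns `male, female`.
#' @examples
#' sex_ratio(356, 203)  # 64 : 36
#' @export
sex_ratio <- function(male_count, female_count) {
  stopifnot(is.numeric(male_count), is.numeric(female_count),
            length(male_count) == length(female_count))
  if (any(male_count < 0 | female_count < 0)) {
    stop("sex_ratio(): negative count")
  }
  tot <- male_count + female_count
  if (any(tot == 0)) stop("sex_ratio(): both counts are zero")
  male <- as.integer(round_half_up(100 * male_count / tot, 0))
  tibble(male = male, female = 100L - male)
}
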