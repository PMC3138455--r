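#' Round half-up
#'
#' Rounds to `digits` decimal places with exact halves rounded away from
#' zero (commercial rounding), e.g. `round_half_up(0.5) == 1`. This is the
#' rounding convention used throughout the package for percentages and
#' ratios; base [round()] uses round-half-even, which does not reproduce
#' conventionally rounded published rates.
#'
#' @param x non-negative numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(68.843, 1)  # 68.8
#' round_half_up(15.5, 0)    # 16
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) {
    stop("round_half_up() is defined for non-negative values only")
  }
  s <- 10^digits
  # guard against values that are decimally exact halves but sit a few ulp
  # below .5 in binary
  floor(round(x * s, 9) + 0.5) / s
}

year_of <- function(d) as.integer(format(d, "%Y"))

parse_iso_date <- function(x) {
  d <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  d
}

trim_upper <- function(x) toupper(trimws(x))

fmt_n <- function(n) formatC(n, format = "d", big.mark = ",")

read_csv_chr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, colClasses = "character", check.names = TRUE,
           stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}
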