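#' @title Clinical code systems and code sets
#' @description Diagnosis and drug-item codes are matched against named
#'   code sets grouped into clinical categories (e.g. "OA", "CVD"). Two
#'   diagnosis coding systems are supported, `ICD9CM` and `ICD10AM`, each
#'   optionally bound to a calendar era so that records coded under the
#'   wrong system for their date can be flagged (Western Australian
#'   hospitals rolled over from ICD-9-CM to ICD-10-AM mid-1999, and the
#'   rollover is a known source of coding inconsistency). Drug item codes
#'   (`DRUG_ITEM`, e.g. PBS item codes) have no era and match exactly.
#' @name codesets
NULL

CODE_SYSTEM_NAMES <- c("ICD9CM", "ICD10AM", "DRUG_ITEM")

#' Define a coding system, optionally bound to a calendar era
#'
#' @param name one of `"ICD9CM"`, `"ICD10AM"`, `"DRUG_ITEM"`.
#' @param era_start,era_end optional `Date` (or ISO-8601 string) bounds of
#'   the period in which the system was the valid coding system. Either
#'   side may be open. `DRUG_ITEM` systems carry no era.
#' @return an object of class `adw_code_system`.
#' @examples
#' code_system("ICD9CM", era_end = "1999-06-30")
#' @seealso [validate_era()], [code_set()]
#' @export
code_system <- function(name, era_start = NULL, era_end = NULL) {
  name <- trim_upper(name)
  if (!name %in% CODE_SYSTEM_NAMES) {
    stop("unknown code system '", name, "'; expected one of: ",
         paste(CODE_SYSTEM_NAMES, collapse = ", "))
  }
  if (!is.null(era_start)) era_start <- as.Date(era_start)
  if (!is.null(era_end)) era_end <- as.Date(era_end)
  if (name == "DRUG_ITEM" && (!is.null(era_start) || !is.null(era_end))) {
    stop("DRUG_ITEM code systems carry no coding era")
  }
  if (!is.null(era_start) && !is.null(era_end) && !(era_start < era_end)) {
    stop("era_start must precede era_end")
  }
  structure(list(name = name, era_start = era_start, era_end = era_end),
            class = "adw_code_system")
}

#' @export
print.adw_code_system <- function(x, ...) {
  era <- if (is.null(x$era_start) && is.null(x$era_end)) {
    "no era"
  } else {
    paste0("era ", x$era_start %||% "-inf", " .. ", x$era_end %||% "+inf")
  }
  cat("<code system ", x$name, "; ", era, ">\n", sep = "")
  invisible(x)
}

#' The default diagnosis coding eras
#'
#' ICD-9-CM until 1999-06-30 and ICD-10-AM from 1999-07-01, the mid-1999
#' rollover used in Australian hospital morbidity collections; drug item
#' codes have no era.
#'
#' @return named list of [code_system()] objects.
#' @export
default_code_systems <- function() {
  list(
    ICD9CM = code_system("ICD9CM", era_end = "1999-06-30"),
    ICD10AM = code_system("ICD10AM", era_start = "1999-07-01"),
    DRUG_ITEM = code_system("DRUG_ITEM")
  )
}

code_syntax_ok <- function(codes, system_name) {
  if (system_name == "DRUG_ITEM") {
    grepl("^[A-Z0-9]+$", codes)
  } else {
    # letter/digit root with an optional dot-suffix
    grepl("^[A-Z0-9]+(\\.[A-Z0-9]+)?$", codes)
  }
}

#' Construct a validated code set
#'
#' A code set is a named clinical category (e.g. `"OA"`, `"CVD"`) bound to
#' one coding system and a non-empty set of codes. Codes are trimmed,
#' upper-cased and de-duplicated (with a warning); syntactically invalid
#' codes raise an error naming the offending entries.
#'
#' @param codes character vector of code tokens.
#' @param category category label.
#' @param system an [code_system()] object (or a system name).
#' @return an object of class `adw_code_set`.
#' @export
code_set <- function(codes, category, system) {
  if (is.character(system)) system <- code_system(system)
  stopifnot(inherits(system, "adw_code_system"))
  category <- trim_upper(category)
  if (!nzchar(category)) stop("code set category must be non-empty")
  codes <- trim_upper(as.character(codes))
  if (length(codes) == 0 || all(!nzchar(codes))) {
    stop("code set '", category, "' (", system$name, ") has no codes")
  }
  bad <- which(!code_syntax_ok(codes, system$name))
  if (length(bad) > 0) {
    stop("invalid ", system$name, " code token(s) in category '", category,
         "' at row(s) ", paste(bad, collapse = ", "), ": ",
         paste(sQuote(codes[bad]), collapse = ", "))
  }
  if (anyDuplicated(codes)) {
    dups <- unique(codes[duplicated(codes)])
    warning("code set '", category, "' (", system$name, "): removed ",
            length(dups), " duplicated code(s): ",
            paste(dups, collapse = ", "))
    codes <- unique(codes)
  }
  structure(list(category = category, system = system, codes = codes),
            class = "adw_code_set")
}

#' @export
print.adw_code_set <- function(x, ...) {
  cat("<code set ", x$category, " [", x$system$name, "]: ",
      length(x$codes), " codes>\n", sep = "")
  cat(" ", paste(head(x$codes, 10), collapse = ", "),
      if (length(x$codes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Load a code set from a CSV file
#'
#' The file must have a `code` column (one code token per row) and may have
#' a free-text `label` column; category and system are supplied by the
#' caller (normally from a manifest entry of the run configuration).
#'
#' @param path CSV file path.
#' @inheritParams code_set
#' @return an `adw_code_set`.
#' @export
load_codeset <- function(path, category, system) {
  df <- read_csv_chr(path)
  require_columns(df, "code", paste0("code-set file ", path))
  if (nrow(df) == 0) stop("code-set file ", path, " contains no codes")
  codes <- trim_upper(df$code)
  if (is.character(system)) system <- code_system(system)
  bad <- which(!code_syntax_ok(codes, system$name) | !nzchar(codes))
  if (length(bad) > 0) {
    stop("code-set file ", path, ": invalid code token(s) at data row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(sQuote(codes[bad]), collapse = ", "))
  }
  code_set(codes, category, system)
}

#' Match record codes against a code set
#'
#' For ICD systems a record code matches when it equals a set member or
#' extends one hierarchically with a dot boundary: a member `"M15"` matches
#' `"M15"` and `"M15.0"` but not `"M150X"`. For `DRUG_ITEM` sets matching
#' is exact string equality. Comparison is case-insensitive after trimming.
#'
#' @param code character vector of record codes (non-empty tokens).
#' @param codeset an [code_set()].
#' @return logical vector parallel to `code`.
#' @examples
#' oa <- code_set(c("M15", "M16"), "OA", "ICD10AM")
#' match_code(c("M15.0", "M150X", "M16"), oa)  # TRUE FALSE TRUE
#' @export
match_code <- function(code, codeset) {
  stopifnot(inherits(codeset, "adw_code_set"))
  code <- trim_upper(as.character(code))
  if (any(!nzchar(code))) stop("match_code(): empty record code")
  if (codeset$system$name == "DRUG_ITEM") {
    return(code %in% codeset$codes)
  }
  prefixes <- paste0(codeset$codes, ".")
  exact <- code %in% codeset$codes
  hier <- vapply(code, function(cc) any(startsWith(cc, prefixes)),
                 logical(1), USE.NAMES = FALSE)
  exact | hier
}

#' Check record dates against a system's coding era
#'
#' Returns `TRUE` for every date when the system has no configured era;
#' otherwise `TRUE` iff the date falls inside the era (inclusive bounds).
#' Callers flag failing records for reporting rather than dropping them
#' silently; the package never remaps codes across the era boundary.
#'
#' @param record_date `Date` vector.
#' @param system an [code_system()].
#' @return logical vector parallel to `record_date`.
#' @export
validate_era <- function(record_date, system) {
  stopifnot(inherits(system, "adw_code_system"))
  record_date <- as.Date(record_date)
  if (any(is.na(record_date))) stop("validate_era(): unparseable date")
  ok <- rep(TRUE, length(record_date))
  if (!is.null(system$era_start)) ok <- ok & record_date >= system$era_start
  if (!is.null(system$era_end)) ok <- ok & record_date <= system$era_end
  ok
}

# union of codes over the sets matching the given categories and system
codes_for <- function(codesets, categories, system_name) {
  hits <- Filter(function(s) {
    s$category %in% categories && s$system$name == system_name
  }, codesets)
  unique(unlist(lapply(hits, `[[`, "codes"), use.names = FALSE)) %||%
    character(0)
}

# a single merged code set for one (category, system), or NULL
merged_set_for <- function(codesets, category, system_name) {
  codes <- codes_for(codesets, category, system_name)
  if (length(codes) == 0) return(NULL)
  suppressWarnings(code_set(codes, category, system_name))
}

codeset_categories <- function(codesets) {
  unique(vapply(codesets, `[[`, character(1), "category"))
}

#' Load a manifest of code-set files
#'
#' @param path CSV with columns `file, category, system`; `file` is
#'   resolved relative to the manifest's directory.
#' @param systems named list of [code_system()] objects supplying eras;
#'   defaults to [default_code_systems()].
#' @return list of `adw_code_set` objects.
#' @export
load_codeset_manifest <- function(path, systems = default_code_systems()) {
  man <- read_csv_chr(path)
  require_columns(man, c("file", "category", "system"),
                  paste0("manifest ", path))
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    sys_name <- trim_upper(man$system[i])
    sys <- systems[[sys_name]] %||% code_system(sys_name)
    load_codeset(file.path(base, man$file[i]), man$category[i], sys)
  })
}

#' Code sets bundled with the package
#'
#' Illustrative placeholder code lists (diagnosis roots and synthetic drug
#' item codes) for the OA/RA target categories and the CVD/CVA/RENAL flag
#' categories, used by the examples, the synthetic-data generator and the
#' test suite. They are *not* curated clinical code lists and must not be
#' used for real analyses.
#'
#' @inheritParams load_codeset_manifest
#' @return list of `adw_code_set` objects.
#' @export
example_codesets <- function(systems = default_code_systems()) {
  load_codeset_manifest(
    system.file("extdata", "codesets", "manifest.csv", package = "adewatch",
                mustWork = TRUE),
    systems = systems
  )
}
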