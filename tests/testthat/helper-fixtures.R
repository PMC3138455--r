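# Shared fixtures and independent brute-force oracles.

library(tibble)
library(dplyr)

CS <- example_codesets()
CFG <- cohort_config(2000)

disp_row <- function(person_id, date, item, age, sex = "F") {
  tibble(person_id = person_id, dispense_date = as.Date(date),
         item_code = item, age = as.integer(age), sex = sex)
}

morb_row <- function(person_id, date, primary, secondary = character(0),
                     age = 70, sex = "F", system = "ICD10AM") {
  tibble(person_id = person_id, separation_date = as.Date(date),
         system = system, primary_dx = primary,
         secondary_dx = list(secondary), age = as.integer(age), sex = sex)
}

empty_disp <- function() disp_row(character(0), character(0), character(0),
                                  integer(0), character(0))
empty_morb <- function() {
  tibble(person_id = character(0), separation_date = as.Date(character(0)),
         system = character(0), primary_dx = character(0),
         secondary_dx = list(), age = integer(0), sex = character(0))
}

# write file-shaped generator output and read it back through the readers
read_generated <- function(gen) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  dp <- file.path(dir, "d.csv"); mp <- file.path(dir, "m.csv")
  utils::write.csv(as.data.frame(gen$dispensing), dp, row.names = FALSE)
  utils::write.csv(as.data.frame(gen$morbidity), mp, row.names = FALSE)
  list(dispensing = read_dispensing(dp), morbidity = read_morbidity(mp))
}

## ---- independent oracles ------------------------------------------------

# equals-or-prefix-at-dot scan, one pair at a time
naive_icd_match <- function(code, members) {
  any(vapply(members, function(m) {
    code == m || startsWith(code, paste0(m, "."))
  }, logical(1)))
}

naive_codes_of <- function(codesets, cat, sysname) {
  out <- character(0)
  for (s in codesets) {
    if (s$category == cat && s$system$name == sysname) {
      out <- c(out, s$codes)
    }
  }
  unique(out)
}

naive_era_ok <- function(sysname, date) {
  if (sysname == "ICD9CM") date <= as.Date("1999-06-30")
  else if (sysname == "ICD10AM") date >= as.Date("1999-07-01")
  else TRUE
}

# per-person loop re-implementation of membership, flags and lattice classes
naive_pipeline <- function(d, m, codesets, config) {
  idx <- config$index_year
  lb_from <- idx - config$lookback_years
  dyr <- as.integer(format(d$dispense_date, "%Y"))
  myr <- as.integer(format(m$separation_date, "%Y"))
  target_items <- unique(unlist(lapply(config$target_categories,
                                       naive_codes_of, codesets = codesets,
                                       sysname = "DRUG_ITEM")))
  persons <- sort(union(d$person_id, m$person_id))
  rows <- lapply(persons, function(p) {
    dp <- d[d$person_id == p, ]; dpy <- dyr[d$person_id == p]
    mp <- m[m$person_id == p, ]; mpy <- myr[m$person_id == p]
    m_ok <- vapply(seq_len(nrow(mp)), function(i) {
      naive_era_ok(mp$system[i], mp$separation_date[i])
    }, logical(1))
    mp_idx <- mp[mpy == idx & m_ok, ]
    dx_codes_row <- lapply(seq_len(nrow(mp_idx)), function(i) {
      c(mp_idx$primary_dx[i], mp_idx$secondary_dx[[i]])
    })
    has_dx_cat <- function(cat) {
      any(vapply(seq_len(nrow(mp_idx)), function(i) {
        members <- naive_codes_of(codesets, cat, mp_idx$system[i])
        any(vapply(dx_codes_row[[i]], naive_icd_match, logical(1),
                   members = members))
      }, logical(1)))
    }
    has_med_cat_win <- function(cat) {
      items <- naive_codes_of(codesets, cat, "DRUG_ITEM")
      any(dp$item_code[dpy >= lb_from & dpy <= idx] %in% items)
    }
    target_med <- any(dp$item_code[dpy == idx] %in% target_items)
    target_dx <- any(vapply(config$target_categories, has_dx_cat,
                            logical(1)))
    idx_ages <- c(dp$age[dpy == idx], mp$age[mpy == idx])
    age <- if (length(idx_ages)) max(idx_ages) else NA_integer_
    member <- (target_med || target_dx) && !is.na(age) &&
      age >= config$min_age
    med_flags <- vapply(config$flag_categories, has_med_cat_win, logical(1))
    dx_flags <- vapply(config$flag_categories, has_dx_cat, logical(1))
    hosp <- nrow(mp_idx) > 0
    med_class <- if (member && target_med) {
      if (any(med_flags)) "TARGET_PLUS_FLAG" else "TARGET_ONLY"
    } else NA_character_
    merged <- if (!member) NA_character_
      else if (target_med && target_dx) "MEDS_AND_TARGET_DX"
      else if (target_med && hosp) "MEDS_AND_NONTARGET_DX"
      else if (target_med) "MEDS_ONLY"
      else "DX_ONLY"
    tibble(person_id = p, member = member, age = age,
           target_med = target_med, target_dx = target_dx,
           hospital = hosp,
           med_flag_any = any(med_flags), dx_flag = list(dx_flags),
           med_flag = list(med_flags),
           med_class = med_class, merged_class = merged)
  })
  bind_rows(rows)
}

# naive per-cell filter-and-count cross-tab oracle
naive_crosstab <- function(profiles, panels, bands) {
  out <- list()
  for (pn in names(panels)) {
    hit <- panels[[pn]](profiles)
    for (b in bands$label) for (s in c("M", "F")) {
      out[[length(out) + 1]] <- tibble(
        band = b, sex = s, panel = pn,
        n = sum(hit & profiles$age_band == b & profiles$sex == s)
      )
    }
  }
  bind_rows(out)
}
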