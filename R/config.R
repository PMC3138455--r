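#' Read a run configuration file
#'
#' A YAML file bundling everything a pipeline run needs: the cohort
#' parameters, the code-set manifest, the drug/indication under study,
#' the body systems of the trials' research questions and the discordance
#' flag threshold. Code-set file paths are resolved relative to the
#' configuration file. See
#' `system.file("extdata", "example_config.yaml", package = "adewatch")`
#' for the bundled example.
#'
#' @param path YAML file path.
#' @return list with components `config` (an [cohort_config()]),
#'   `codesets` (list of [code_set()]), `drug`, `indication`,
#'   `target_systems`, `flag_threshold`, `criteria_file` (path or `NULL`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("run config not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(path)

  systems <- default_code_systems()
  if (!is.null(y$eras)) {
    for (nm in names(y$eras)) {
      e <- y$eras[[nm]]
      systems[[trim_upper(nm)]] <- code_system(
        nm, era_start = e$start %||% NULL, era_end = e$end %||% NULL)
    }
  }
  config <- cohort_config(
    index_year = y$index_year %||% stop("run config: index_year required"),
    min_age = y$min_age %||% 65L,
    lookback_years = y$lookback_years %||% 1L,
    high_use_threshold = y$high_use_threshold %||% 3000L,
    target_categories = unlist(y$target_categories %||% c("OA", "RA")),
    flag_categories = unlist(y$flag_categories %||%
                               c("CVD", "CVA", "RENAL")),
    systems = systems
  )
  codesets <- if (!is.null(y$codesets)) {
    lapply(y$codesets, function(cs) {
      sys_name <- trim_upper(cs$system)
      load_codeset(file.path(base, cs$file), cs$category,
                   systems[[sys_name]] %||% code_system(sys_name))
    })
  } else {
    example_codesets(systems = systems)
  }
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  list(
    config = config,
    codesets = codesets,
    drug = y$drug %||% "unspecified drug",
    indication = trim_upper(y$indication %||%
                              config$target_categories[1]),
    target_systems = unlist(y$target_systems %||% "musculoskeletal"),
    flag_threshold = y$flag_threshold %||% 10,
    criteria_file = resolve(y$criteria_file)
  )
}
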