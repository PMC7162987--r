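#' Read and write study configuration files
#'
#' A study configuration is stored as plain-text YAML with one section per
#' component: top-level scalars (`n_subjects`, `seed`, `mad_threshold`,
#' `truncate`, `time_coding`, `icc_sessions`), a `population` section with
#' one `mean`/`sd` pair per observer parameter, and an optional `battery`
#' section of per-task overrides.
#'
#' @param cfg a [study_config()] (for writing).
#' @param path file path.
#' @return `read_study_config()` returns a [study_config()];
#'   `write_study_config()` returns `path` invisibly.
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  out <- list(
    n_subjects = cfg$n_subjects,
    seed = cfg$seed,
    mad_threshold = cfg$mad_threshold,
    truncate = cfg$truncate,
    time_coding = cfg$time_coding,
    icc_sessions = cfg$icc_sessions,
    population = lapply(seq_len(nrow(cfg$population)), function(i) {
      list(parameter = cfg$population$parameter[i],
           mean = cfg$population$mean[i], sd = cfg$population$sd[i])
    }),
    battery = cfg$battery_overrides
  )
  yaml::write_yaml(out[!vapply(out, is.null, TRUE)], path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: %s", path))
  raw <- yaml::read_yaml(path)
  population <- default_population()
  if (!is.null(raw$population)) {
    population <- purrr::map(raw$population, as_tibble) %>% list_rbind()
  }
  study_config(
    n_subjects = raw$n_subjects %||% 15,
    seed = raw$seed %||% 1,
    population = population,
    battery_overrides = raw$battery,
    mad_threshold = raw$mad_threshold %||% 2.5,
    icc_sessions = unlist(raw$icc_sessions),
    truncate = raw$truncate %||% TRUE,
    time_coding = raw$time_coding %||% "linear"
  )
}

#' Write the session-calibrated measure-generator configuration
#'
#' Emits a ready-made YAML file with the thirteen measure specifications of
#' [default_measure_specs()] (per-session means/SDs and within-subject CVs),
#' the calibration the measure-level generator uses.
#'
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measure_config <- function(path) {
  specs <- default_measure_specs()
  out <- lapply(seq_len(nrow(specs)), function(i) {
    r <- specs[i, ]
    list(task = r$task, measure = r$measure, units = r$units,
         session_means = c(r$m1, r$m2, r$m3),
         session_sds = c(r$s1, r$s2, r$s3),
         cv_ws = r$cv_ws)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_measure_config
#' @export
read_measure_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: %s", path))
  raw <- yaml::read_yaml(path)
  purrr::map(raw, function(r) {
    tibble(task = r$task, measure = r$measure, units = r$units,
           m1 = r$session_means[1], s1 = r$session_sds[1],
           m2 = r$session_means[2], s2 = r$session_sds[2],
           m3 = r$session_means[3], s3 = r$session_sds[3],
           cv_ws = r$cv_ws)
  }) %>% list_rbind()
}
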