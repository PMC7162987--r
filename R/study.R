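#' Configuration of a simulated reliability study
#'
#' @param n_subjects number of simulated subjects (≥ 2).
#' @param seed master seed; every stream in the study is derived from it
#'   deterministically, so a config plus seed fully determines all output.
#' @param population observer population, as [default_population()].
#' @param battery_overrides optional per-task overrides passed to
#'   [default_battery()].
#' @param mad_threshold MAD outlier threshold used in the analysis.
#' @param icc_sessions optional version subset for the ICC (e.g.
#'   `c("Short1", "Short2")`).
#' @param truncate recompute long-version measures after truncation to the
#'   short trial count (the "Short(3)" re-analysis)?
#' @param time_coding `"linear"` (session index as a slope) or
#'   `"categorical"` for the time-effect models.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 15, seed = 1,
                         population = default_population(),
                         battery_overrides = NULL,
                         mad_threshold = 2.5,
                         icc_sessions = NULL,
                         truncate = TRUE,
                         time_coding = c("linear", "categorical")) {
  stopifnot_scalar_number(n_subjects, "n_subjects", positive = TRUE)
  if (n_subjects < 2) abort("Reliability analysis needs at least 2 subjects.")
  stopifnot_scalar_number(seed, "seed")
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         population = population, battery_overrides = battery_overrides,
         mad_threshold = mad_threshold, icc_sessions = icc_sessions,
         truncate = truncate, time_coding = match.arg(time_coding)),
    class = "study_config"
  )
}

measure_units <- function(task, measure) {
  if (measure %in% c("rt_median", "rt_isv")) return("ms")
  if (measure == "convergence") return("count")
  switch(task,
         sDT = , dDT = , nAD = , dAD = , sAD = "um",
         sqFD = , smFD = "Hz",
         TOJs = , TOJc = "ms",
         "")
}

#' Run the full in-silico study
#'
#' Samples an observer population, randomizes version order across subjects,
#' runs every task of every session through the staircase engine (with
#' per-session multiplicative jitter on each observer's latent parameters),
#' and assembles the tidy measure records. Child seeds are derived by
#' hashing (master seed, subject, session, task), so the result is
#' bit-identical under a fixed master seed and adding a task never perturbs
#' the streams of the others.
#'
#' @param cfg a [study_config()].
#' @return A tibble of class `study_dataset` with columns `subject_id`,
#'   `session_index`, `version`, `task`, `measure`, `value`, `units`, and
#'   the trial-level records attached as `attr(, "trials")`.
#' @export
#'
#' @examples
#' \donttest{
#' ds <- run_study(study_config(n_subjects = 4, seed = 1))
#' dplyr::count(ds, measure)
#' }
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  schedule <- make_schedule(cfg$n_subjects, child_seed(cfg$seed, "schedule"))
  observers <- sample_population(cfg$population, cfg$n_subjects,
                                 child_seed(cfg$seed, "population"))
  batteries <- list(short = default_battery("short", cfg$battery_overrides),
                    long = default_battery("long", cfg$battery_overrides))
  subjects <- unique(schedule$subject_id)
  measure_rows <- list()
  trial_rows <- list()
  for (i in seq_along(subjects)) {
    subj <- subjects[i]
    obs <- observers[[i]]
    sched_i <- schedule[schedule$subject_id == subj, ]
    for (r in seq_len(nrow(sched_i))) {
      sess <- sched_i$session_index[r]
      version <- sched_i$version[r]
      specs <- if (version == "Long") batteries$long else batteries$short
      obs_sess <- jitter_observer(obs, child_seed(cfg$seed, "jitter", subj, sess))
      for (spec in specs) {
        res <- run_task(spec, obs_sess,
                        child_seed(cfg$seed, "task", subj, sess, spec$task_id))
        key <- paste(subj, sess, spec$task_id)
        measure_rows[[key]] <- imap(res$measures, function(v, nm) {
          tibble(subject_id = subj, session_index = sess, version = version,
                 task = spec$task_id, measure = nm, value = as.numeric(v),
                 units = measure_units(spec$task_id, nm))
        }) %>% list_rbind()
        trial_rows[[key]] <- res$trials %>%
          mutate(subject_id = subj, session_index = sess, version = version,
                 task = spec$task_id, .before = 1)
      }
    }
  }
  ds <- list_rbind(measure_rows) %>%
    arrange(.data$subject_id, .data$session_index, .data$task, .data$measure)
  attr(ds, "trials") <- list_rbind(trial_rows)
  class(ds) <- c("study_dataset", class(ds))
  ds
}

#' Trial-level records of a simulated study
#'
#' @param ds a `study_dataset` from [run_study()].
#' @return Tibble of per-trial records, or `NULL` when the dataset was read
#'   from a measures file without trial data.
#' @export
study_trials <- function(ds) attr(ds, "trials")

# Recompute long-version measures after truncating each long run to the
# short trial count, returning a measures tibble with Long rows replaced.
truncated_measures <- function(ds, cfg) {
  trials <- study_trials(ds)
  if (is.null(trials)) return(NULL)
  short_n <- vapply(default_battery("short", cfg$battery_overrides),
                    function(s) s$n_trials, 1L)
  long_specs <- default_battery("long", cfg$battery_overrides)
  long_trials <- trials %>% filter(.data$version == "Long")
  groups <- long_trials %>% distinct(.data$subject_id, .data$session_index,
                                     .data$task)
  rows <- purrr::pmap(groups, function(subject_id, session_index, task) {
    tr <- long_trials %>%
      filter(.data$subject_id == !!subject_id,
             .data$session_index == !!session_index,
             .data$task == !!task) %>%
      arrange(.data$trial)
    tr <- tr[seq_len(min(short_n[[task]], nrow(tr))), ]
    meas <- compute_measures(long_specs[[task]], tr)
    imap(meas, function(v, nm) {
      tibble(subject_id = subject_id, session_index = session_index,
             version = "Long", task = task, measure = nm,
             value = as.numeric(v), units = measure_units(task, nm))
    }) %>% list_rbind()
  })
  bind_rows(ds %>% filter(.data$version != "Long") %>% as_tibble(),
            list_rbind(rows))
}

# Collapse the two short instances into one version level for modelling.
collapse_version <- function(v) ifelse(v == "Long", "long", "short")

# Version-effect and time-effect LRTs for one (task, measure) slice.
single_effect_tests <- function(d, time_coding) {
  out <- list()
  d <- d %>% mutate(version_c = factor(collapse_version(.data$version),
                                       levels = c("short", "long")),
                    time = if (time_coding == "linear") .data$session_index
                           else factor(.data$session_index))
  red <- fit_lmm(d, value ~ 1)
  if (length(unique(d$version_c)) > 1) {
    full_v <- fit_lmm(d, value ~ version_c)
    out$version <- lrt(full_v, red) %>%
      mutate(effect = "version", effect_size = effect_size(full_v, red),
             .before = 1)
  }
  full_t <- fit_lmm(d, value ~ time)
  out$time <- lrt(full_t, red) %>%
    mutate(effect = "time", effect_size = effect_size(full_t, red),
           .before = 1)
  list_rbind(out)
}

# Task-effect comparison within one domain (a set of tasks sharing a
# measure), adjusting for version as a nuisance fixed effect.
domain_task_test <- function(d, time_coding) {
  d <- d %>% mutate(task = factor(.data$task),
                    version_c = factor(collapse_version(.data$version),
                                       levels = c("short", "long")))
  full <- fit_lmm(d, value ~ task + version_c)
  red <- fit_lmm(d, value ~ version_c)
  test <- lrt(full, red) %>%
    mutate(effect = "task", effect_size = effect_size(full, red), .before = 1)
  contrasts <- if (nlevels(d$task) >= 3) tukey_posthoc(full, "task") else NULL
  list(test = test, contrasts = contrasts, fit = full)
}

#' Full reliability analysis of a study dataset
#'
#' Reproduces the complete analysis pipeline on a tidy study dataset:
#' the per-task reliability table (MAD screening, per-session and pooled
#' mean ± SD and between-subject CV, within-subject CV, ICC(A,k)); the same
#' table after truncating long runs to the short trial count (when
#' trial-level records are attached and truncation is enabled); Bland-Altman
#' quantities for every version pair; random-intercept mixed-model tests of
#' version and time effects per task measure; task-effect comparisons within
#' each domain (reaction time, detection, amplitude discrimination,
#' frequency discrimination, temporal order) with Tukey-Holm contrasts where
#' a domain has three tasks; and the corresponding models for convergence
#' scores.
#'
#' @param ds a `study_dataset` (from [run_study()] or [read_dataset()]).
#' @param cfg a [study_config()]; analysis options are taken from it.
#' @return An object of class `study_report`: a list with elements
#'   `reliability`, `reliability_truncated`, `bland_altman`,
#'   `version_time_effects`, `domain_effects`, `convergence_effects`.
#' @export
analyze_study <- function(ds, cfg = study_config(n_subjects = max(2, length(unique(ds$subject_id))))) {
  stopifnot(is.data.frame(ds))
  report <- list(config = cfg)
  report$reliability <- reliability_table(
    ds %>% filter(.data$measure != "convergence"),
    icc_sessions = cfg$icc_sessions, mad_threshold = cfg$mad_threshold)
  report$reliability_truncated <- NULL
  if (isTRUE(cfg$truncate)) {
    trunc <- truncated_measures(ds, cfg)
    if (!is.null(trunc)) {
      report$reliability_truncated <- reliability_table(
        trunc %>% filter(.data$measure != "convergence"),
        icc_sessions = cfg$icc_sessions, mad_threshold = cfg$mad_threshold)
    }
  }
  # Bland-Altman quantities per (task, measure) per version pair
  primary <- ds %>% filter(.data$measure != "convergence")
  pairs <- list(c("Short1", "Short2"), c("Short1", "Long"), c("Short2", "Long"))
  report$bland_altman <- purrr::map(pairs, function(pr) {
    wide <- primary %>%
      filter(.data$version %in% pr) %>%
      select("subject_id", "task", "measure", "version", "value") %>%
      pivot_wider(names_from = "version", values_from = "value") %>%
      filter(!is.na(.data[[pr[1]]]), !is.na(.data[[pr[2]]]))
    if (nrow(wide) == 0) return(NULL)
    suppressWarnings(
      dplyr::bind_cols(
        wide %>% select("subject_id", "task", "measure"),
        bland_altman(wide[[pr[1]]], wide[[pr[2]]])
      ) %>% mutate(pair = paste(pr, collapse = " vs "), .before = 1)
    )
  }) %>% list_rbind()
  # Version and time effects per (task, measure)
  vt <- primary %>% distinct(.data$task, .data$measure)
  report$version_time_effects <- purrr::pmap(vt, function(task, measure) {
    d <- primary[primary$task == task & primary$measure == measure, ]
    if (nrow(d) < 6) return(NULL)
    tryCatch(
      single_effect_tests(d, cfg$time_coding) %>%
        mutate(task = task, measure = measure, .before = 1),
      error = function(e) {
        warn(sprintf("Version/time models failed for %s/%s: %s",
                     task, measure, conditionMessage(e)))
        NULL
      })
  }) %>% list_rbind()
  # Domain comparisons
  domains <- list(
    rt = list(tasks = c("sRT", "cRT"), measure = "rt_median"),
    rt_isv = list(tasks = c("sRT", "cRT"), measure = "rt_isv"),
    dt = list(tasks = c("sDT", "dDT"), measure = "threshold"),
    ad = list(tasks = c("nAD", "dAD", "sAD"), measure = "threshold"),
    fd = list(tasks = c("sqFD", "smFD"), measure = "threshold"),
    toj = list(tasks = c("TOJs", "TOJc"), measure = "threshold")
  )
  report$domain_effects <- purrr::imap(domains, function(dom, nm) {
    d <- primary %>% filter(.data$task %in% dom$tasks,
                            .data$measure == dom$measure)
    if (length(unique(d$task)) < 2) return(NULL)
    tryCatch(domain_task_test(d, cfg$time_coding), error = function(e) {
      warn(sprintf("Domain comparison '%s' failed: %s", nm,
                   conditionMessage(e)))
      NULL
    })
  })
  # Convergence-score models
  conv <- ds %>% filter(.data$measure == "convergence")
  report$convergence_effects <- NULL
  if (nrow(conv) > 0 && length(unique(conv$task)) >= 2) {
    res <- domain_task_test(conv, cfg$time_coding)
    vt_conv <- single_effect_tests(conv, cfg$time_coding)
    report$convergence_effects <- list(task = res, version_time = vt_conv,
                                       mean_score = mean(conv$value),
                                       sd_score = sd(conv$value))
  }
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  reliability rows: %d\n", nrow(x$reliability)))
  if (!is.null(x$reliability_truncated)) {
    cat(sprintf("  truncated-long rows: %d\n", nrow(x$reliability_truncated)))
  }
  icc <- x$reliability %>% select("task", "measure", "icc")
  print(as.data.frame(icc), row.names = FALSE)
  if (!is.null(x$convergence_effects)) {
    cat(sprintf("  mean convergence score: %.2f +/- %.2f\n",
                x$convergence_effects$mean_score, x$convergence_effects$sd_score))
  }
  invisible(x)
}

#' Write a study report to CSV files plus a text summary
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$reliability, file.path(dir, "reliability.csv"))
  if (!is.null(report$reliability_truncated)) {
    readr::write_csv(report$reliability_truncated,
                     file.path(dir, "reliability_truncated.csv"))
  }
  if (!is.null(report$bland_altman)) {
    readr::write_csv(report$bland_altman, file.path(dir, "bland_altman.csv"))
  }
  if (!is.null(report$version_time_effects)) {
    readr::write_csv(report$version_time_effects,
                     file.path(dir, "version_time_effects.csv"))
  }
  contrasts <- purrr::imap(report$domain_effects, function(de, nm) {
    if (is.null(de)) return(NULL)
    de$test %>% mutate(domain = nm, .before = 1)
  }) %>% list_rbind()
  if (nrow(contrasts) > 0) {
    readr::write_csv(contrasts, file.path(dir, "domain_effects.csv"))
  }
  ad <- report$domain_effects$ad
  if (!is.null(ad) && !is.null(ad$contrasts)) {
    readr::write_csv(ad$contrasts, file.path(dir, "ad_contrasts.csv"))
  }
  summary_path <- file.path(dir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(report)), con)
  invisible(dir)
}

dataset_columns <- c("subject_id", "session_index", "version", "task",
                     "measure", "value", "units")

#' Read and write tidy study datasets
#'
#' The measures CSV is the interchange format between simulation and
#' analysis: columns `subject_id`, `session_index`, `version`, `task`,
#' `measure`, `value`, `units`, one row per measurement, with
#' `(subject_id, session_index, task, measure)` unique.
#'
#' @param ds a `study_dataset` (for writing).
#' @param path CSV file path.
#' @return `read_dataset()` returns a `study_dataset` tibble;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  readr::write_csv(as_tibble(ds)[, dataset_columns], path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (file.size(path) == 0) {
    warn("Empty dataset file; returning an empty dataset.")
    ds <- tibble(subject_id = character(), session_index = integer(),
                 version = character(), task = character(),
                 measure = character(), value = double(), units = character())
    class(ds) <- c("study_dataset", class(ds))
    return(ds)
  }
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(.default = "c")))
  missing_cols <- setdiff(dataset_columns, header)
  if (length(missing_cols) > 0) {
    abort(paste("Dataset file is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  ds <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    session_index = readr::col_integer(),
    version = readr::col_character(),
    task = readr::col_character(),
    measure = readr::col_character(),
    value = readr::col_double(),
    units = readr::col_character()
  ))
  problems <- readr::problems(ds)
  if (nrow(problems) > 0) {
    abort(sprintf("Malformed dataset at line %d: %s",
                  problems$row[1], problems$expected[1]))
  }
  dup <- ds %>%
    dplyr::count(.data$subject_id, .data$session_index, .data$task,
                 .data$measure) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "Duplicate (subject, session, task, measure) keys, e.g. %s/%s/%s/%s.",
      dup$subject_id[1], dup$session_index[1], dup$task[1], dup$measure[1]))
  }
  if (nrow(ds) == 0) warn("Dataset file contains a header but no records.")
  class(ds) <- c("study_dataset", class(ds))
  ds
}

#' Write trial-level records to CSV
#'
#' @param ds a `study_dataset` carrying trial records.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(ds, path) {
  trials <- study_trials(ds)
  if (is.null(trials)) abort("Dataset carries no trial-level records.")
  readr::write_csv(trials, path)
  invisible(path)
}
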