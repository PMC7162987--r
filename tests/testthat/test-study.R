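test_that("a default-sized study produces the full record set", {
  ds <- cached_study() # 15 subjects x 3 sessions x 11 tasks
  counts <- dplyr::count(ds, measure)
  n_of <- function(m) counts$n[counts$measure == m]
  # one primary measure per task instance: threshold for 9 tasks,
  # median RT for the 2 reaction-time tasks
  expect_equal(n_of("threshold") + n_of("rt_median"), 495L)
  expect_equal(n_of("rt_isv"), 90L)       # 2 RT tasks x 45 sessions
  expect_equal(n_of("convergence"), 360L) # 8 staircase tasks x 45 sessions
  expect_true(all(ds$session_index %in% 1:3))
  expect_setequal(unique(ds$version), c("Short1", "Short2", "Long"))
  # key uniqueness
  expect_equal(nrow(dplyr::distinct(ds, subject_id, session_index, task,
                                    measure)), nrow(ds))
  trials <- study_trials(ds)
  expect_true(all(c("subject_id", "session_index", "version", "task", "trial",
                    "level", "target_site", "response_site", "correct",
                    "rt_ms", "amp_at_press_um") %in% names(trials)))
})

test_that("a study is byte-identical under its master seed", {
  cfg <- study_config(n_subjects = 3, seed = 77)
  d1 <- run_study(cfg)
  d2 <- run_study(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_identical(study_trials(d1), study_trials(d2))
  d3 <- run_study(study_config(n_subjects = 3, seed = 78))
  expect_false(identical(d1$value, d3$value))
})

test_that("datasets round-trip through the measures CSV", {
  ds <- run_study(study_config(n_subjects = 2, seed = 5))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_dataset(ds, path)
  back <- read_dataset(path)
  expected <- ds
  attr(expected, "trials") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(expected))

  # duplicate keys are rejected
  dup <- dplyr::bind_rows(tibble::as_tibble(ds), tibble::as_tibble(ds)[1, ])
  readr::write_csv(dup, path)
  expect_error(read_dataset(path), "Duplicate")

  # an empty file warns and yields an empty dataset
  writeLines(character(), path)
  expect_warning(empty <- read_dataset(path), "Empty")
  expect_equal(nrow(empty), 0L)

  # missing columns are named
  readr::write_csv(dplyr::select(tibble::as_tibble(ds), -units)[, 1:5], path)
  expect_error(read_dataset(path), "missing columns")
})

test_that("the analysis report mirrors the study's thirteen measure rows", {
  ds <- cached_study()
  cfg <- study_config(n_subjects = 15, seed = 20260901)
  report <- analyze_study(ds, cfg)
  expect_s3_class(report, "study_report")
  expect_equal(nrow(report$reliability), 13L)
  expect_setequal(
    paste(report$reliability$task, report$reliability$measure),
    c("sRT rt_median", "sRT rt_isv", "cRT rt_median", "cRT rt_isv",
      "sDT threshold", "dDT threshold", "nAD threshold", "dAD threshold",
      "sAD threshold", "sqFD threshold", "smFD threshold",
      "TOJs threshold", "TOJc threshold"))
  expect_true(all(report$reliability$icc >= 0 & report$reliability$icc <= 1,
                  na.rm = TRUE))
  # truncated re-analysis present and same shape
  expect_equal(nrow(report$reliability_truncated), 13L)
  # Bland-Altman covers the three version pairs
  expect_setequal(unique(report$bland_altman$pair),
                  c("Short1 vs Short2", "Short1 vs Long", "Short2 vs Long"))
  # amplitude-discrimination domain gets Tukey contrasts (3 tasks)
  expect_equal(nrow(report$domain_effects$ad$contrasts), 3L)
  expect_null(report$domain_effects$dt$contrasts)
  # convergence models cover the 8 staircase tasks
  expect_equal(nlevels(factor(
    stats::model.frame(report$convergence_effects$task$fit$model)$task)), 8L)
  expect_true(report$convergence_effects$mean_score >= 0 &&
                report$convergence_effects$mean_score <= 5)
})

test_that("truncation re-analysis is gated by the config", {
  ds <- run_study(study_config(n_subjects = 4, seed = 9))
  cfg_off <- study_config(n_subjects = 4, seed = 9, truncate = FALSE)
  report <- analyze_study(ds, cfg_off)
  expect_null(report$reliability_truncated)
})

test_that("a zero-residual measure dataset yields ICC 1 throughout the report", {
  spec <- measure_spec("toy", c(10, 10, 10), c(3, 3, 3), cv_ws = 0)
  ds <- measures_dataset(spec, 10, seed = 40, task = "sDT")
  # degenerate (zero-residual) data: mixed models may fail and warn
  report <- suppressWarnings(
    analyze_study(ds, study_config(n_subjects = 10, truncate = FALSE)))
  expect_equal(report$reliability$icc, 1, tolerance = 1e-9)
})

test_that("truncated long measures match direct truncation of the trials", {
  ds <- run_study(study_config(n_subjects = 3, seed = 13))
  cfg <- study_config(n_subjects = 3, seed = 13)
  trunc <- vibrotact:::truncated_measures(ds, cfg)
  trials <- study_trials(ds)
  one <- trials[trials$version == "Long" & trials$task == "sDT" &
                  trials$subject_id == "S01", ]
  one <- one[order(one$trial), ][1:24, ]
  expect_equal(
    trunc$value[trunc$version == "Long" & trunc$task == "sDT" &
                  trunc$subject_id == "S01" & trunc$measure == "threshold"],
    mean(one$level[20:24]))
  # short-version rows are untouched
  short_rows <- trunc[trunc$version != "Long", ]
  orig_rows <- tibble::as_tibble(ds)[ds$version != "Long", ]
  expect_equal(sort(short_rows$value), sort(orig_rows$value))
})

test_that("study and measure configs round-trip through YAML", {
  cfg <- study_config(n_subjects = 7, seed = 123, mad_threshold = 3,
                      icc_sessions = c("Short1", "Short2"),
                      truncate = FALSE, time_coding = "categorical")
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(back$n_subjects, 7L)
  expect_equal(back$seed, 123L)
  expect_equal(back$mad_threshold, 3)
  expect_equal(back$icc_sessions, c("Short1", "Short2"))
  expect_false(back$truncate)
  expect_equal(back$time_coding, "categorical")
  expect_equal(as.data.frame(back$population), as.data.frame(cfg$population))

  mpath <- tempfile(fileext = ".yaml")
  on.exit(unlink(mpath), add = TRUE)
  write_measure_config(mpath)
  specs <- read_measure_config(mpath)
  expect_equal(as.data.frame(specs), as.data.frame(default_measure_specs()),
               tolerance = 1e-12)
})

test_that("plots build without error", {
  obs <- observer_params()
  res <- run_task(default_battery("short")$sDT, obs, seed = 2)
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
  ds <- run_study(study_config(n_subjects = 4, seed = 3))
  report <- analyze_study(ds, study_config(n_subjects = 4, seed = 3))
  expect_s3_class(plot_bland_altman(report$bland_altman, tasks = "sDT"),
                  "ggplot")
  expect_s3_class(plot_reliability(report$reliability), "ggplot")
})

test_that("reports are written as CSVs plus a text summary", {
  ds <- run_study(study_config(n_subjects = 4, seed = 3))
  report <- analyze_study(ds, study_config(n_subjects = 4, seed = 3))
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  write_report(report, dir)
  expect_true(file.exists(file.path(dir, "reliability.csv")))
  expect_true(file.exists(file.path(dir, "reliability_truncated.csv")))
  expect_true(file.exists(file.path(dir, "bland_altman.csv")))
  expect_true(file.exists(file.path(dir, "version_time_effects.csv")))
  expect_true(file.exists(file.path(dir, "summary.txt")))
  expect_gt(length(readLines(file.path(dir, "summary.txt"))), 2)
})
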