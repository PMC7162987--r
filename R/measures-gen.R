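#' Specification of one measure's session-level distribution
#'
#' Describes the statistical structure the reliability analysis assumes for
#' one task measure: per-session population means and SDs plus the
#' within-subject coefficient of variation. [sample_measures()] turns such a
#' specification into subject-by-session data with matching variance
#' components.
#'
#' @param measure measure name (e.g. `"sDT"`).
#' @param session_means numeric vector of per-session means.
#' @param session_sds numeric vector of per-session SDs (same length).
#' @param cv_ws within-subject coefficient of variation, in percent.
#' @param units measurement units (metadata).
#' @return An object of class `measure_spec`.
#' @export
measure_spec <- function(measure, session_means, session_sds, cv_ws,
                         units = "") {
  if (length(session_means) != length(session_sds)) {
    abort("session_means and session_sds must have the same length.")
  }
  if (any(session_sds < 0) || cv_ws < 0) {
    abort("SDs and cv_ws must be non-negative.")
  }
  if (any(session_means <= 0)) {
    abort("session_means must be strictly positive.")
  }
  structure(
    list(measure = measure, session_means = session_means,
         session_sds = session_sds, cv_ws = cv_ws, units = units),
    class = "measure_spec"
  )
}

#' Session-level calibration of the thirteen battery measures
#'
#' Per-session means, SDs and within-subject CVs for the eleven task
#' measures plus the two reaction-time ISV measures, as published for the
#' adult battery. These are the default calibration of the measure-level
#' generator.
#'
#' @return A tibble with columns `task`, `measure`, `units`, `m1`, `s1`,
#'   `m2`, `s2`, `m3`, `s3` (per-session mean/SD for Short1, Short2 and
#'   Long) and `cv_ws` (percent).
#' @export
default_measure_specs <- function() {
  tibble(
    task = c("sRT", "sRT", "cRT", "cRT", "sDT", "dDT", "nAD", "dAD",
             "sAD", "sqFD", "smFD", "TOJs", "TOJc"),
    measure = c("rt_median", "rt_isv", "rt_median", "rt_isv", "threshold",
                "threshold", "threshold", "threshold", "threshold",
                "threshold", "threshold", "threshold", "threshold"),
    units = c("ms", "ms", "ms", "ms", "um", "um", "um", "um", "um",
              "Hz", "Hz", "ms", "ms"),
    m1 = c(217.75, 50.42, 434.83, 78.55, 5.51, 7.94, 38.13, 19.86, 50.27,
           7.03, 7.37, 27.79, 30.65),
    s1 = c(51.34, 19.07, 112.31, 30.51, 2.10, 1.90, 21.74, 11.83, 29.29,
           2.50, 2.59, 12.79, 14.33),
    m2 = c(212.46, 47.67, 430.87, 67.71, 5.17, 9.03, 37.87, 23.29, 52.27,
           7.15, 8.97, 26.52, 44.63),
    s2 = c(49.09, 18.52, 93.13, 23.70, 1.45, 2.16, 18.01, 11.65, 22.46,
           2.59, 3.87, 13.06, 19.59),
    m3 = c(216.10, 46.06, 417.10, 73.61, 4.61, 7.93, 25.23, 22.71, 46.67,
           6.40, 7.12, 18.12, 29.51),
    s3 = c(56.05, 17.57, 78.64, 31.01, 2.70, 1.38, 13.63, 15.00, 23.12,
           4.04, 4.15, 11.08, 22.07),
    cv_ws = c(10.85, 23.41, 9.50, 26.53, 30.85, 13.48, 40.45, 45.71, 31.44,
              41.72, 36.96, 45.94, 35.93)
  )
}

# Coerce one row of default_measure_specs() (or a measure_spec) to measure_spec.
as_measure_spec <- function(x) {
  if (inherits(x, "measure_spec")) return(x)
  if (is.data.frame(x) && nrow(x) == 1L) {
    return(measure_spec(
      measure = paste(x$task, x$measure, sep = "_"),
      session_means = c(x$m1, x$m2, x$m3),
      session_sds = c(x$s1, x$s2, x$s3),
      cv_ws = x$cv_ws, units = x$units
    ))
  }
  abort("Expected a measure_spec or a one-row specification data frame.")
}

#' Generate a subject-by-session measure matrix with given variance structure
#'
#' Decomposes the target structure into additive components and draws
#' `entry(i, j) = grand mean + b_i + c_j + e_ij` with normal subject effects
#' `b_i`, fixed session effects `c_j = mu_j - grand mean`, and normal
#' residuals `e_ij`. The residual SD is `cv_ws/100` times the grand mean;
#' the subject-effect variance is the mean per-session variance minus the
#' residual variance (clamped at zero with a warning when the implied value
#' is negative). Generated values are clamped to be strictly positive.
#'
#' @param spec a [measure_spec()] or a one-row tibble from
#'   [default_measure_specs()].
#' @param n_subjects number of subjects.
#' @param n_sessions number of sessions (at most the number of session means
#'   in `spec`).
#' @param seed optional integer seed.
#' @return A numeric matrix `[n_subjects x n_sessions]` with session labels
#'   as column names.
#' @export
#'
#' @examples
#' spec <- measure_spec("toy", c(10, 10, 10), c(2, 2, 2), cv_ws = 10)
#' m <- sample_measures(spec, n_subjects = 15, seed = 1)
#' icc_avg_absolute(m)
sample_measures <- function(spec, n_subjects, n_sessions = NULL, seed = NULL) {
  spec <- as_measure_spec(spec)
  stopifnot_scalar_number(n_subjects, "n_subjects", positive = TRUE)
  k_avail <- length(spec$session_means)
  n_sessions <- n_sessions %||% k_avail
  if (n_sessions > k_avail) {
    abort(sprintf("Requested %d sessions but spec provides %d session means.",
                  n_sessions, k_avail))
  }
  mu <- spec$session_means[seq_len(n_sessions)]
  s <- spec$session_sds[seq_len(n_sessions)]
  grand <- mean(mu)
  sigma_w <- spec$cv_ws / 100 * grand
  var_b <- mean(s^2) - sigma_w^2
  if (var_b < 0) {
    warn(sprintf(
      "Measure '%s': implied subject-effect variance %.4g is negative; clamped to 0.",
      spec$measure, var_b))
    var_b <- 0
  }
  with_seed(seed, {
    b <- rnorm(n_subjects, 0, sqrt(var_b))
    e <- matrix(rnorm(n_subjects * n_sessions, 0, sigma_w),
                n_subjects, n_sessions)
    m <- grand + outer(b, mu - grand, `+`) + e
    m <- pmax(m, .Machine$double.eps)
    colnames(m) <- paste0("session", seq_len(n_sessions))
    m
  })
}
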