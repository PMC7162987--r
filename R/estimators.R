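#' Threshold from the final five staircase trials
#'
#' The threshold estimate is the arithmetic mean of the tracked levels
#' *presented* on the final five trials of the run.
#'
#' @param trials a trials tibble with columns `trial` and `level`.
#' @return Threshold in tracked-quantity units.
#' @export
estimate_threshold <- function(trials) {
  if (nrow(trials) < 5L) {
    abort("Need at least 5 trials to estimate a threshold.")
  }
  mean(tail(trials$level[order(trials$trial)], 5L))
}

#' Median reaction time
#'
#' @param trials a trials tibble with columns `rt_ms` and `correct`.
#' @param correct_only restrict to correct trials (choice reaction time).
#' @return Median reaction time in ms.
#' @export
estimate_rt <- function(trials, correct_only = FALSE) {
  rts <- if (correct_only) trials$rt_ms[trials$correct] else trials$rt_ms
  rts <- rts[!is.na(rts)]
  if (length(rts) < 1L) {
    abort("No qualifying trials for a reaction-time estimate.")
  }
  median(rts)
}

#' Intrasubject variability (ISV) of reaction times
#'
#' Sample standard deviation of the trial-level reaction times after
#' screening them with the median-absolute-deviation rule
#' ([mad_outliers()], threshold 2.5).
#'
#' @param trials a trials tibble with column `rt_ms`.
#' @param mad_threshold outlier threshold on the robust z score.
#' @return ISV in ms.
#' @export
estimate_isv <- function(trials, mad_threshold = 2.5) {
  rts <- trials$rt_ms[!is.na(trials$rt_ms)]
  if (length(rts) >= 3L) {
    rts <- rts[!mad_outliers(rts, mad_threshold)]
  }
  if (length(rts) < 3L) {
    abort("Need at least 3 reaction times after outlier removal for ISV.")
  }
  sd(rts)
}

#' Dynamic detection threshold
#'
#' Mean ramp amplitude at the moment of the button press, across correct
#' trials only; no reaction-time correction is applied.
#'
#' @param trials a trials tibble with columns `amp_at_press_um` and `correct`.
#' @return Threshold in μm.
#' @export
estimate_ddt <- function(trials) {
  amps <- trials$amp_at_press_um[trials$correct]
  amps <- amps[!is.na(amps)]
  if (length(amps) < 1L) {
    abort("No correct trials: dynamic detection threshold undefined.")
  }
  mean(amps)
}

#' Convergence score of a staircase run
#'
#' Number of correct responses among the final five trials (the trials used
#' to estimate the threshold). A score of 5 means no inaccurate responses in
#' those trials; 0 means no accurate response.
#'
#' @param trials a trials tibble with columns `trial` and `correct`.
#' @return Integer in 0–5.
#' @export
convergence_score <- function(trials) {
  if (nrow(trials) < 5L) {
    abort("Need at least 5 trials for a convergence score.")
  }
  sum(tail(trials$correct[order(trials$trial)], 5L))
}
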