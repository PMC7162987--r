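#' Initialize a transformed up-down staircase
#'
#' @param spec a [task_spec()] with a tracked quantity.
#' @return An object of class `staircase_state` with fields `level`, `phase`
#'   (`"1u1d"` or `"2u1d"`), `consecutive_correct`, `trial_index`, `step`,
#'   `floor` and `switch_trial`.
#' @export
new_staircase <- function(spec) {
  if (spec$tracked_quantity == "none") {
    abort(sprintf("Task %s has no tracked quantity.", spec$task_id))
  }
  structure(
    list(level = spec$initial_tracked_value,
         phase = "1u1d",
         consecutive_correct = 0L,
         trial_index = 0L,
         step = spec$step_size,
         floor = spec$floor_level,
         switch_trial = spec$switch_trial),
    class = "staircase_state"
  )
}

#' Advance a staircase by one response
#'
#' Applies the transformed up-down tracking rule. During the one-up/one-down
#' phase (the first `switch_trial` trials) the level decreases by one step
#' after a correct response and increases by one step after an incorrect one.
#' In the two-up/one-down phase two consecutive correct responses are needed
#' for a decrease; any incorrect response increases the level and resets the
#' consecutive-correct counter. The level never drops below the floor. The
#' two-up/one-down rule converges on the stimulus level yielding
#' 2^(-1/2) ≈ 70.7% correct.
#'
#' @param state a `staircase_state`.
#' @param correct logical; was the response on this trial correct?
#' @return The updated `staircase_state`, with `trial_index` advanced and
#'   `phase` reflecting the rule that will apply to the *next* trial.
#' @export
#'
#' @examples
#' st <- new_staircase(default_battery("short")$sDT)
#' update_staircase(st, TRUE)$level  # 20 - 2
update_staircase <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  if (state$phase == "1u1d") {
    state$level <- if (correct) state$level - state$step else state$level + state$step
  } else {
    if (!correct) {
      state$level <- state$level + state$step
      state$consecutive_correct <- 0L
    } else if (state$consecutive_correct == 0L) {
      state$consecutive_correct <- 1L
    } else {
      state$level <- state$level - state$step
      state$consecutive_correct <- 0L
    }
  }
  state$level <- max(state$level, state$floor)
  state$trial_index <- state$trial_index + 1L
  state$phase <- if (state$trial_index < state$switch_trial) "1u1d" else "2u1d"
  state
}

#' Run one task for one simulated observer
#'
#' Executes the complete trial loop of a task: target sites are drawn
#' pseudorandomly per trial, responses come from the observer model
#' ([trial_response()]), tracking tasks update the staircase with
#' [update_staircase()], reaction-time tasks record response times, and the
#' dynamic-detection task draws a pre-ramp delay uniformly and records the
#' ramp amplitude at the moment of the button press. All per-task measures
#' are then computed.
#'
#' @param spec a [task_spec()].
#' @param observer an [observer_params()] object.
#' @param seed optional integer seed; a fixed seed makes the result
#'   bit-identical across runs.
#' @return An object of class `task_result`: a list with `task_id`,
#'   `version`, `spec`, `trials` (a tibble with one row per trial) and
#'   `measures` (named list; see [compute_measures()]).
#' @export
#'
#' @examples
#' obs <- observer_params(response_policy = "always_correct")
#' res <- run_task(default_battery("short")$sDT, obs, seed = 1)
#' res$measures$threshold
run_task <- function(spec, observer, seed = NULL) {
  stopifnot(inherits(spec, "task_spec"), inherits(observer, "observer_params"))
  with_seed(seed, {
    n <- spec$n_trials
    tracking <- spec$tracked_quantity != "none"
    state <- if (tracking) new_staircase(spec)
    targets <- sample(c("LD2", "LD3"), n, replace = TRUE)
    level <- rep(NA_real_, n)
    response_site <- character(n)
    correct <- logical(n)
    rt_ms <- rep(NA_real_, n)
    amp <- rep(NA_real_, n)
    for (t in seq_len(n)) {
      if (tracking) level[t] <- state$level
      resp <- trial_response(spec, level[t], observer)
      response_site[t] <- if (resp$site_choice) {
        if (resp$correct) targets[t] else setdiff(c("LD2", "LD3"), targets[t])
      } else "any"
      correct[t] <- resp$correct
      rt_ms[t] <- resp$rt_ms
      amp[t] <- resp$amp_at_press_um
      if (tracking) state <- update_staircase(state, resp$correct)
    }
    trials <- tibble(
      trial = seq_len(n), level = level, target_site = targets,
      response_site = response_site, correct = correct, rt_ms = rt_ms,
      amp_at_press_um = amp
    )
    structure(
      list(task_id = spec$task_id, version = spec$version, spec = spec,
           trials = trials, measures = compute_measures(spec, trials)),
      class = "task_result"
    )
  })
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("<task_result> %s (%s), %d trials\n", x$task_id, x$version,
              nrow(x$trials)))
  m <- x$measures[!vapply(x$measures, is.na, TRUE)]
  cat(paste(sprintf("  %s = %.4g", names(m), unlist(m)), collapse = "\n"), "\n")
  invisible(x)
}

#' Compute all measures a task yields from its trial records
#'
#' Tracking tasks yield a threshold (mean presented level of the final five
#' trials) and a convergence score; reaction-time tasks yield the median
#' reaction time (correct trials only for choice reaction time) and the
#' intrasubject variability (ISV); dynamic detection yields the mean ramp
#' amplitude at the button press over correct trials.
#'
#' @param spec a [task_spec()].
#' @param trials a trials tibble as produced by [run_task()].
#' @return Named list with elements among `threshold`, `rt_median`, `rt_isv`
#'   and `convergence` (absent measures are omitted).
#' @export
compute_measures <- function(spec, trials) {
  out <- list()
  if (spec$tracked_quantity != "none") {
    out$threshold <- estimate_threshold(trials)
    out$convergence <- convergence_score(trials)
  } else if (spec$task_id == "dDT") {
    out$threshold <- estimate_ddt(trials)
  } else {
    out$rt_median <- estimate_rt(trials, correct_only = spec$task_id == "cRT")
    out$rt_isv <- estimate_isv(trials)
  }
  out
}

#' Truncate a long-version run and recompute its measures
#'
#' Keeps the first `n_short` trials in presentation order and recomputes
#' every measure on the truncated trial list, emulating a "Short(3)"
#' administration extracted from a long one.
#'
#' @param result a `task_result` from a long-version run.
#' @param n_short number of trials to keep (defaults to half the run).
#' @return A `task_result` with truncated trials and recomputed measures.
#' @export
truncate_long <- function(result, n_short = nrow(result$trials) %/% 2L) {
  stopifnot(inherits(result, "task_result"))
  if (n_short > nrow(result$trials)) {
    abort(sprintf("Cannot truncate to %d trials: run has only %d.",
                  n_short, nrow(result$trials)))
  }
  result$trials <- result$trials[seq_len(n_short), , drop = FALSE]
  result$measures <- compute_measures(result$spec, result$trials)
  result
}
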