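#' Construct the specification of a single battery task
#'
#' A task specification carries every constant needed to run one paradigm of
#' the eleven-task vibrotactile battery: stimulus parameters, trial counts,
#' the quantity that the adaptive staircase tracks (if any), its starting
#' value, step size and floor, and the trial at which tracking switches from
#' one-up/one-down to two-up/one-down.
#'
#' @param task_id one of `"sRT"`, `"cRT"`, `"sDT"`, `"dDT"`, `"nAD"`,
#'   `"dAD"`, `"sAD"`, `"sqFD"`, `"smFD"`, `"TOJs"`, `"TOJc"`.
#' @param version `"short"` or `"long"`.
#' @param n_trials number of test trials.
#' @param iti intertrial interval in seconds (metadata; no clock is modelled).
#' @param tracked_quantity what the staircase adjusts: `"amplitude"` (μm),
#'   `"amplitude_difference"` (μm), `"frequency_difference"` (Hz),
#'   `"isi"` (ms) or `"none"` for reaction-time and ramp tasks.
#' @param initial_tracked_value starting value of the tracked quantity.
#' @param standard_value value of the standard stimulus where the task has
#'   one (100 μm for amplitude discrimination, 30 Hz for frequency
#'   discrimination), otherwise `NA`.
#' @param step_size staircase step in tracked-quantity units.
#' @param switch_trial trial after which tracking becomes two-up/one-down.
#' @param floor_level lowest value the staircase may present.
#' @param stimulus named list with `frequency` (Hz), `amplitude` (μm) and
#'   `duration` (ms) of the test stimulus.
#' @param adaptor optional named list describing an adapting stimulus.
#' @param carrier optional named list describing a concurrent carrier.
#' @param ramp_rate amplitude ramp rate in μm/s (dynamic detection only).
#' @param pre_ramp_delay_range two-element delay interval in ms (dynamic
#'   detection only).
#' @param isi_ms interstimulus interval in ms for sequential presentation.
#'
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(task_id, version, n_trials, iti,
                      tracked_quantity = "none",
                      initial_tracked_value = NA_real_,
                      standard_value = NA_real_,
                      step_size = NA_real_,
                      switch_trial = 10L,
                      floor_level = NA_real_,
                      stimulus = list(frequency = 25, amplitude = 300, duration = 40),
                      adaptor = NULL,
                      carrier = NULL,
                      ramp_rate = NA_real_,
                      pre_ramp_delay_range = NULL,
                      isi_ms = NA_real_) {
  task_ids <- c("sRT", "cRT", "sDT", "dDT", "nAD", "dAD", "sAD",
                "sqFD", "smFD", "TOJs", "TOJc")
  if (!task_id %in% task_ids) {
    abort(sprintf("Unknown task_id '%s'.", task_id))
  }
  if (!version %in% c("short", "long")) {
    abort(sprintf("Unknown version '%s': must be 'short' or 'long'.", version))
  }
  stopifnot_scalar_number(n_trials, "n_trials", positive = TRUE)
  tracked <- c("none", "amplitude", "amplitude_difference",
               "frequency_difference", "isi")
  if (!tracked_quantity %in% tracked) {
    abort(sprintf("Unknown tracked_quantity '%s'.", tracked_quantity))
  }
  with(stimulus, {
    stopifnot_scalar_number(frequency, "stimulus$frequency", positive = TRUE)
    stopifnot_scalar_number(amplitude, "stimulus$amplitude", positive = TRUE)
    stopifnot_scalar_number(duration, "stimulus$duration", positive = TRUE)
  })
  if (tracked_quantity != "none") {
    stopifnot_scalar_number(initial_tracked_value, "initial_tracked_value",
                            positive = TRUE)
    stopifnot_scalar_number(step_size, "step_size", positive = TRUE)
    stopifnot_scalar_number(floor_level, "floor_level", positive = TRUE)
    if (!(initial_tracked_value > floor_level)) {
      abort("initial_tracked_value must exceed floor_level.")
    }
  }
  structure(
    list(task_id = task_id, version = version,
         n_trials = as.integer(n_trials), iti = iti,
         tracked_quantity = tracked_quantity,
         initial_tracked_value = initial_tracked_value,
         standard_value = standard_value,
         step_size = step_size,
         switch_trial = as.integer(switch_trial),
         floor_level = floor_level,
         stimulus = stimulus, adaptor = adaptor, carrier = carrier,
         ramp_rate = ramp_rate,
         pre_ramp_delay_range = pre_ramp_delay_range,
         isi_ms = isi_ms),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s (%s): %d trials", x$task_id, x$version, x$n_trials))
  if (x$tracked_quantity != "none") {
    cat(sprintf(", tracks %s from %g by %g (floor %g)",
                x$tracked_quantity, x$initial_tracked_value,
                x$step_size, x$floor_level))
  }
  cat("\n")
  invisible(x)
}

# Canonical constants of the eleven paradigms. Short-version trial counts
# and all stimulus parameters follow the published battery; the long
# version doubles trial counts and, for nAD only, starts the comparison at
# 300 instead of 200 μm (an idiosyncrasy of the original study kept here).
# Step sizes default to 10% of the initial tracked value; floors to one step.
battery_constants <- function() {
  list(
    sRT  = list(n_short = 20L, iti = 3,
                stimulus = list(frequency = 25, amplitude = 300, duration = 40)),
    cRT  = list(n_short = 20L, iti = 3,
                stimulus = list(frequency = 25, amplitude = 300, duration = 40)),
    sDT  = list(n_short = 24L, iti = 5, tracked = "amplitude",
                initial = 20, step = 2, floor = 2,
                stimulus = list(frequency = 25, amplitude = 20, duration = 500)),
    # dDT ramps from zero; amplitude/duration give a nominal ramp ceiling.
    dDT  = list(n_short = 7L, iti = 10, ramp_rate = 2,
                pre_ramp_delay_range = c(0, 2500),
                stimulus = list(frequency = 25, amplitude = 300, duration = 150000)),
    nAD  = list(n_short = 20L, iti = 5, tracked = "amplitude_difference",
                initial = 100, initial_long = 200, standard = 100,
                step = 10, step_long = 20, floor = 10, floor_long = 20,
                stimulus = list(frequency = 25, amplitude = 200, duration = 500)),
    dAD  = list(n_short = 20L, iti = 5, tracked = "amplitude_difference",
                initial = 100, standard = 100, step = 10, floor = 10,
                stimulus = list(frequency = 25, amplitude = 200, duration = 500),
                adaptor = list(frequency = 25, amplitude = 100, duration = 1000,
                               sites = "dual")),
    sAD  = list(n_short = 20L, iti = 5, tracked = "amplitude_difference",
                initial = 100, standard = 100, step = 10, floor = 10,
                stimulus = list(frequency = 25, amplitude = 200, duration = 500),
                adaptor = list(frequency = 25, amplitude = 100, duration = 1000,
                               sites = "single")),
    sqFD = list(n_short = 20L, iti = 5, tracked = "frequency_difference",
                initial = 10, standard = 30, step = 1, floor = 1, isi_ms = 500,
                stimulus = list(frequency = 30, amplitude = 200, duration = 500)),
    smFD = list(n_short = 20L, iti = 5, tracked = "frequency_difference",
                initial = 10, standard = 30, step = 1, floor = 1,
                stimulus = list(frequency = 30, amplitude = 200, duration = 500)),
    TOJs = list(n_short = 20L, iti = 5, tracked = "isi",
                initial = 150, step = 15, floor = 15,
                stimulus = list(frequency = 25, amplitude = 200, duration = 40)),
    TOJc = list(n_short = 20L, iti = 5, tracked = "isi",
                initial = 150, step = 15, floor = 15,
                stimulus = list(frequency = 25, amplitude = 200, duration = 40),
                carrier = list(frequency = 25, amplitude = 20, duration = 1000))
  )
}

#' Canonical task order of the battery
#'
#' The task order is fixed within a session (and across sessions).
#'
#' @return Character vector of the eleven task identifiers in battery order.
#' @export
battery_task_order <- function() {
  c("sRT", "cRT", "sDT", "dDT", "nAD", "dAD", "sAD",
    "sqFD", "smFD", "TOJs", "TOJc")
}

#' Default parameterization of the eleven-task battery
#'
#' Returns the canonical task specifications for one version of the battery.
#' The long version doubles every short trial count; the long no-adaptation
#' amplitude-discrimination task starts the comparison stimulus at 300 μm
#' (initial tracked difference 200 μm) rather than 200 μm, reproducing the
#' original study's configuration.
#'
#' @param version `"short"` or `"long"`.
#' @param overrides optional named list of per-task field overrides, e.g.
#'   `list(sDT = list(n_trials = 100, step_size = 0.5))`. Fields must be
#'   `task_spec` arguments.
#'
#' @return A named list of eleven [task_spec()] objects in battery order.
#' @export
#'
#' @examples
#' specs <- default_battery("short")
#' specs$sDT$n_trials
default_battery <- function(version = c("short", "long"), overrides = NULL) {
  version <- match.arg(version)
  consts <- battery_constants()
  long <- identical(version, "long")
  specs <- lapply(battery_task_order(), function(id) {
    cc <- consts[[id]]
    tracked <- cc$tracked %||% "none"
    initial <- if (long) cc$initial_long %||% cc$initial else cc$initial
    step <- if (long) cc$step_long %||% cc$step else cc$step
    floor <- if (long) cc$floor_long %||% cc$floor else cc$floor
    args <- list(
      task_id = id, version = version,
      n_trials = if (long) 2L * cc$n_short else cc$n_short,
      iti = cc$iti,
      tracked_quantity = tracked,
      initial_tracked_value = initial %||% NA_real_,
      standard_value = cc$standard %||% NA_real_,
      step_size = step %||% NA_real_,
      floor_level = floor %||% NA_real_,
      stimulus = cc$stimulus,
      adaptor = cc$adaptor,
      carrier = cc$carrier,
      ramp_rate = cc$ramp_rate %||% NA_real_,
      pre_ramp_delay_range = cc$pre_ramp_delay_range,
      isi_ms = cc$isi_ms %||% NA_real_
    )
    if (!is.null(overrides[[id]])) {
      args[names(overrides[[id]])] <- overrides[[id]]
    }
    do.call(task_spec, args)
  })
  names(specs) <- battery_task_order()
  specs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Randomize version order across subjects
#'
#' Each subject completes the battery three times: twice in its short form
#' (the instances Short1 and Short2) and once in its long form. The order of
#' the three instances across sessions is randomized per subject, drawing a
#' permutation of the three version labels uniformly.
#'
#' @param n_subjects number of subjects (≥ 1).
#' @param seed optional integer seed for reproducible schedules.
#'
#' @return A tibble with columns `subject_id`, `session_index` (1–3) and
#'   `version` (`"Short1"`, `"Short2"`, `"Long"`).
#' @export
#'
#' @examples
#' make_schedule(3, seed = 1)
make_schedule <- function(n_subjects, seed = NULL) {
  stopifnot_scalar_number(n_subjects, "n_subjects", positive = TRUE)
  versions <- c("Short1", "Short2", "Long")
  with_seed(seed, {
    purrr::map(seq_len(n_subjects), function(i) {
      tibble(subject_id = sprintf("S%02d", i),
             session_index = 1:3,
             version = sample(versions))
    }) %>% list_rbind()
  })
}

#' Read or write a battery configuration file
#'
#' Battery constants are exportable to (and overridable from) a plain-text
#' YAML file with one section per task whose keys mirror [task_spec()]
#' arguments. `read_battery_config()` returns an overrides list suitable for
#' `default_battery(overrides = )`.
#'
#' @param specs a list of [task_spec()] objects (for writing).
#' @param path file path.
#' @return `read_battery_config()` returns a named list of per-task override
#'   lists; `write_battery_config()` returns `path` invisibly.
#' @export
write_battery_config <- function(specs, path) {
  as_plain <- function(s) {
    s <- unclass(s)
    s[!vapply(s, is.null, TRUE)]
  }
  yaml::write_yaml(lapply(specs, as_plain), path)
  invisible(path)
}

#' @rdname write_battery_config
#' @export
read_battery_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("Battery config must contain one section per task.")
  cfg
}
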