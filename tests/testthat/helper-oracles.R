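# Shared test fixtures and independent oracles.

# Independent ICC(A,k) oracle: mean squares from a brute-force two-way
# ANOVA via stats::aov, entirely separate from the package's closed-form
# computation.
icc_oracle <- function(m) {
  d <- data.frame(
    value = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), times = ncol(m))),
    session = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  ms <- summary(aov(value ~ subject + session, data = d))[[1]][["Mean Sq"]]
  ms_r <- ms[1]; ms_c <- ms[2]; ms_e <- ms[3]
  (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / nrow(m))
}

# Deterministic observers for worked checks of tracking and scoring rules.
perfect_observer <- function(...) {
  observer_params(response_policy = "always_correct", ...)
}
hopeless_observer <- function(...) {
  observer_params(response_policy = "always_incorrect", ...)
}

# A noiseless observer: zero lapse, no session jitter, no ramp noise.
quiet_observer <- function(...) {
  observer_params(
    lambda = 0, ddt_noise_sd = 0,
    session_jitter = c(rt = 0, sdt = 0, ddt = 0, ad = 0, fd = 0, toj = 0),
    ...
  )
}

# Tidy measure dataset from the measure-level generator, with the three
# version labels as sessions; used to feed reliability_table directly.
measures_dataset <- function(spec, n_subjects, seed, task = "toy",
                             measure = "threshold") {
  m <- sample_measures(spec, n_subjects, seed = seed)
  versions <- c("Short1", "Short2", "Long")
  tibble::tibble(
    subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), times = ncol(m)),
    session_index = rep(seq_len(ncol(m)), each = n_subjects),
    version = rep(versions[seq_len(ncol(m))], each = n_subjects),
    task = task, measure = measure, value = as.vector(m), units = ""
  )
}

# One cached default simulated study, shared by bookkeeping tests.
cached_study <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- run_study(study_config(n_subjects = 15, seed = 20260901))
    ds
  }
})
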