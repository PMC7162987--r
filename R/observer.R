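#' Probability of a correct two-alternative response
#'
#' Two-alternative forced-choice performance as a function of the (gained)
#' stimulus difference. The function rises monotonically from chance (0.5)
#' at zero difference to a lapse-limited ceiling of `1 - lambda`, and is
#' calibrated so that its value at `difference = theta` is exactly
#' 2^(-1/2) ≈ 0.7071 — the convergence point of two-up/one-down tracking —
#' so a staircase run against this observer converges on `theta` by
#' construction. The default family is a Weibull in the difference; a
#' logistic alternative is available.
#'
#' @param difference non-negative stimulus difference in tracked units.
#' @param theta the observer's true threshold (difference at 70.71% correct).
#' @param beta psychometric slope (shape of the Weibull / steepness of the
#'   logistic).
#' @param lambda lapse rate in `[0, 0.1]`.
#' @param family `"weibull"` (default) or `"logistic"`.
#' @return Probability in `[0.5, 1 - lambda]`.
#' @export
#'
#' @examples
#' psychometric_correct_prob(0, theta = 5)        # chance
#' psychometric_correct_prob(5, theta = 5)        # 0.7071
psychometric_correct_prob <- function(difference, theta, beta = 2,
                                      lambda = 0.02,
                                      family = c("weibull", "logistic")) {
  family <- match.arg(family)
  if (any(theta <= 0)) abort("`theta` must be strictly positive.")
  if (any(difference < 0)) abort("`difference` must be non-negative.")
  if (any(lambda < 0 | lambda > 0.1)) abort("`lambda` must lie in [0, 0.1].")
  target <- 2^(-1/2)
  # Inner function F in [0, 1); P = 0.5 + (0.5 - lambda) F. Solve F(theta)
  # so that P(theta) = 2^(-1/2) regardless of lambda.
  f_theta <- (target - 0.5) / (0.5 - lambda)
  if (family == "weibull") {
    kappa <- -log(1 - f_theta)
    f <- 1 - exp(-kappa * (difference / theta)^beta)
  } else {
    # scaled logistic through 0 at difference 0
    l <- function(u) 2 / (1 + exp(-u)) - 1
    u_theta <- log((1 + f_theta) / (1 - f_theta))
    f <- l(u_theta * (difference / theta)^beta)
  }
  0.5 + (0.5 - lambda) * f
}

#' Parameters of one simulated observer
#'
#' Latent quantities generating a subject's task performance: true thresholds
#' for each tracked domain, multiplicative adaptation/carrier gains that map
#' a presented difference onto an effective one, the psychometric shape, a
#' log-normal reaction-time model, and per-measure session jitter.
#'
#' Gains act on the presented tracked value, `effective = level * gain`, so
#' a staircase converges on `theta / gain`: single-site adaptation
#' (`gain_single < 1`) raises the measured amplitude-discrimination
#' threshold, dual-site adaptation (`gain_dual > 1`) lowers it, and a carrier
#' stimulus (`gain_carrier < 1`) raises the temporal-order threshold.
#'
#' @param theta_sdt static detection threshold, μm.
#' @param theta_ddt dynamic (ramp) detection threshold, μm.
#' @param theta_ad amplitude-difference threshold (no adaptation), μm.
#' @param gain_single,gain_dual single-/dual-site adaptation gains
#'   (`gain_single < 1 < gain_dual`).
#' @param theta_fd frequency-difference threshold, Hz.
#' @param gain_smfd gain applied in simultaneous frequency discrimination.
#' @param theta_toj temporal-order threshold, ms.
#' @param gain_carrier gain applied under the carrier stimulus (< 1).
#' @param beta psychometric slope.
#' @param lambda lapse rate in `[0, 0.1]`.
#' @param rt_meanlog,rt_sdlog log-normal reaction-time location/scale (ln ms).
#' @param crt_increment_ms additive decision cost for choice reaction time.
#' @param motor_delay_s motor delay between ramp detection and button press.
#' @param ddt_noise_sd log-scale trial noise on the ramp crossing.
#' @param session_jitter named numeric vector of log-scale session jitter
#'   SDs per domain (`rt`, `sdt`, `ddt`, `ad`, `fd`, `toj`).
#' @param family psychometric family, `"weibull"` or `"logistic"`.
#' @param response_policy `"psychometric"` (default) or the deterministic
#'   policies `"always_correct"` / `"always_incorrect"` used for worked
#'   checks of the tracking and scoring rules.
#'
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(theta_sdt = 5.1, theta_ddt = 7.9,
                            theta_ad = 34,
                            gain_single = 34 / 50, gain_dual = 34 / 22,
                            theta_fd = 6.9, gain_smfd = 6.9 / 7.8,
                            theta_toj = 24, gain_carrier = 24 / 35,
                            beta = 2, lambda = 0.02,
                            rt_meanlog = log(215), rt_sdlog = 0.22,
                            crt_increment_ms = 212,
                            motor_delay_s = 0.2, ddt_noise_sd = 0.12,
                            session_jitter = c(rt = 0.08, sdt = 0.25,
                                               ddt = 0.10, ad = 0.32,
                                               fd = 0.32, toj = 0.32),
                            family = "weibull",
                            response_policy = c("psychometric",
                                                "always_correct",
                                                "always_incorrect")) {
  response_policy <- match.arg(response_policy)
  for (nm in c("theta_sdt", "theta_ddt", "theta_ad", "theta_fd", "theta_toj")) {
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  }
  if (!(gain_single < 1 && gain_dual > 1)) {
    abort("Adaptation gains must satisfy gain_single < 1 < gain_dual.")
  }
  if (lambda < 0 || lambda > 0.1) abort("`lambda` must lie in [0, 0.1].")
  structure(
    list(theta_sdt = theta_sdt, theta_ddt = theta_ddt, theta_ad = theta_ad,
         gain_single = gain_single, gain_dual = gain_dual,
         theta_fd = theta_fd, gain_smfd = gain_smfd,
         theta_toj = theta_toj, gain_carrier = gain_carrier,
         beta = beta, lambda = lambda,
         rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
         crt_increment_ms = crt_increment_ms,
         motor_delay_s = motor_delay_s, ddt_noise_sd = ddt_noise_sd,
         session_jitter = session_jitter,
         family = family, response_policy = response_policy),
    class = "observer_params"
  )
}

# Threshold and gain an observer applies to a given task.
task_params <- function(observer, task_id) {
  switch(task_id,
         sDT  = list(theta = observer$theta_sdt, gain = 1),
         nAD  = list(theta = observer$theta_ad, gain = 1),
         dAD  = list(theta = observer$theta_ad, gain = observer$gain_dual),
         sAD  = list(theta = observer$theta_ad, gain = observer$gain_single),
         sqFD = list(theta = observer$theta_fd, gain = 1),
         smFD = list(theta = observer$theta_fd, gain = observer$gain_smfd),
         TOJs = list(theta = observer$theta_toj, gain = 1),
         TOJc = list(theta = observer$theta_toj, gain = observer$gain_carrier),
         abort(sprintf("Observer has no tracking parameters for task '%s'.",
                       task_id)))
}

#' Simulate one trial response
#'
#' Maps a presented tracked level through the task's gain onto an effective
#' difference, draws correctness from the observer's psychometric function,
#' and draws a reaction time from the observer's log-normal model where the
#' task records one. For the dynamic-detection ramp the amplitude at the
#' button press is the threshold crossing plus the ramp travelled during the
#' motor delay, perturbed by log-normal trial noise.
#'
#' @param spec a [task_spec()].
#' @param level currently tracked value (ignored for non-tracking tasks).
#' @param observer an [observer_params()].
#' @return A list with `correct`, `site_choice` (does correctness mean
#'   choosing a site), `rt_ms` and `amp_at_press_um`.
#' @export
trial_response <- function(spec, level, observer) {
  policy <- observer$response_policy
  draw_correct <- function(p) {
    switch(policy,
           psychometric = runif(1) < p,
           always_correct = TRUE,
           always_incorrect = FALSE)
  }
  id <- spec$task_id
  if (id == "sRT") {
    return(list(correct = TRUE, site_choice = FALSE,
                rt_ms = rlnorm(1, observer$rt_meanlog, observer$rt_sdlog),
                amp_at_press_um = NA_real_))
  }
  if (id == "cRT") {
    p <- psychometric_correct_prob(spec$stimulus$amplitude, observer$theta_sdt,
                                   observer$beta, observer$lambda,
                                   observer$family)
    return(list(correct = draw_correct(p), site_choice = TRUE,
                rt_ms = rlnorm(1, observer$rt_meanlog, observer$rt_sdlog) +
                  observer$crt_increment_ms,
                amp_at_press_um = NA_real_))
  }
  if (id == "dDT") {
    delay <- runif(1, spec$pre_ramp_delay_range[1], spec$pre_ramp_delay_range[2])
    amp <- (observer$theta_ddt +
              spec$ramp_rate * observer$motor_delay_s) *
      exp(rnorm(1, 0, observer$ddt_noise_sd))
    p <- psychometric_correct_prob(amp, observer$theta_sdt,
                                   observer$beta, observer$lambda,
                                   observer$family)
    rt <- delay + 1000 * amp / spec$ramp_rate
    return(list(correct = draw_correct(p), site_choice = TRUE,
                rt_ms = rt, amp_at_press_um = amp))
  }
  tp <- task_params(observer, id)
  p <- psychometric_correct_prob(level * tp$gain, tp$theta,
                                 observer$beta, observer$lambda,
                                 observer$family)
  list(correct = draw_correct(p), site_choice = TRUE,
       rt_ms = NA_real_, amp_at_press_um = NA_real_)
}

# Multiplicative log-normal session perturbation of an observer's latent
# parameters, one draw per domain per session.
jitter_observer <- function(observer, seed = NULL) {
  with_seed(seed, {
    j <- observer$session_jitter
    g <- function(dom) exp(rnorm(1, 0, j[[dom]]))
    observer$theta_sdt <- observer$theta_sdt * g("sdt")
    observer$theta_ddt <- observer$theta_ddt * g("ddt")
    observer$theta_ad <- observer$theta_ad * g("ad")
    observer$theta_fd <- observer$theta_fd * g("fd")
    observer$theta_toj <- observer$theta_toj * g("toj")
    observer$rt_meanlog <- observer$rt_meanlog + rnorm(1, 0, j[["rt"]])
    observer
  })
}

#' Default observer population
#'
#' Population means and between-subject SDs for every observer parameter,
#' calibrated so that a default simulated study lands near published adult
#' norms for this battery: grand-mean static detection ≈ 5.1 μm, dynamic
#' detection ≈ 8.3 μm, amplitude-discrimination thresholds ordered
#' single-site > none > dual-site (≈ 50 > 34 > 22 μm), frequency
#' discrimination ≈ 7 Hz, and temporal-order thresholds with carrier above
#' without (≈ 35 > 24 ms).
#'
#' @return A tibble with columns `parameter`, `mean`, `sd`.
#' @export
default_population <- function() {
  tribble_pop <- tibble(
    parameter = c("theta_sdt", "theta_ddt", "theta_ad", "gain_single",
                  "gain_dual", "theta_fd", "gain_smfd", "theta_toj",
                  "gain_carrier", "beta", "lambda", "rt_meanlog",
                  "rt_sdlog", "crt_increment_ms", "motor_delay_s",
                  "ddt_noise_sd"),
    mean = c(5.1, 7.9, 34, 34 / 50, 34 / 22, 6.9, 6.9 / 7.8, 24, 24 / 35,
             2, 0.02, log(215), 0.22, 212, 0.2, 0.12),
    sd = c(1.8, 1.7, 15, 0.05, 0.15, 2.6, 0.06, 10, 0.08,
           0.2, 0.01, 0.22, 0.05, 60, 0.03, 0.02)
  )
  tribble_pop
}

#' Draw a population of simulated observers
#'
#' Parameters are drawn independently from truncated normal distributions
#' (resampling any non-positive draw) around the supplied population means
#' and between-subject SDs. Lapse rates are additionally capped at 0.1 and
#' adaptation gains kept on the correct side of 1.
#'
#' @param population a tibble like [default_population()] with columns
#'   `parameter`, `mean`, `sd`.
#' @param n number of observers.
#' @param seed optional integer seed.
#' @param ... further arguments passed to every [observer_params()] call
#'   (e.g. `session_jitter`).
#' @return A list of `n` [observer_params()] objects.
#' @export
sample_population <- function(population = default_population(), n,
                              seed = NULL, ...) {
  stopifnot_scalar_number(n, "n", positive = TRUE)
  if (any(population$sd < 0)) abort("Population SDs must be non-negative.")
  with_seed(seed, {
    draw_pos <- function(mu, sigma) {
      if (sigma == 0) return(mu)
      x <- rnorm(1, mu, sigma)
      while (x <= 0) x <- rnorm(1, mu, sigma)
      x
    }
    lapply(seq_len(n), function(i) {
      par <- setNames(
        mapply(draw_pos, population$mean, population$sd),
        population$parameter
      )
      par[["lambda"]] <- min(par[["lambda"]], 0.1)
      par[["gain_single"]] <- min(par[["gain_single"]], 0.99)
      par[["gain_dual"]] <- max(par[["gain_dual"]], 1.01)
      do.call(observer_params, c(as.list(par), list(...)))
    })
  })
}
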