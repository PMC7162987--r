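#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' Fits `y = X beta + s_subject + e`, with a normal random intercept per
#' subject and normal residuals, by maximum likelihood (not REML). This is
#' the repeated-measures model used throughout the battery comparisons; the
#' fixed part typically carries a version, time or task predictor.
#'
#' @param data data frame containing the model variables.
#' @param formula model formula for the fixed part, e.g. `value ~ version`.
#' @param subject name of the grouping column (default `"subject_id"`).
#' @return An object of class `lmm_fit`: a list with `beta` (named fixed
#'   effects), `sigma_s2` (random-intercept variance), `sigma_e2` (residual
#'   variance), `loglik`, `n_par`, `n_obs`, `formula` and the underlying
#'   `lme4` fit in `$model`.
#' @export
#'
#' @examples
#' d <- data.frame(subject_id = rep(1:10, each = 3),
#'                 x = rnorm(30), y = rnorm(30))
#' fit <- fit_lmm(d, y ~ x)
#' glance(fit)
fit_lmm <- function(data, formula, subject = "subject_id") {
  if (!subject %in% names(data)) {
    abort(sprintf("Grouping column '%s' not found.", subject))
  }
  if (length(unique(data[[subject]])) < 2L) {
    abort("Need at least 2 subjects for a random-intercept model.")
  }
  full_formula <- stats::as.formula(
    paste(deparse(formula), sprintf("+ (1 | %s)", subject))
  )
  fit <- suppressMessages(lme4::lmer(
    full_formula, data = data, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  ))
  vc <- lme4::VarCorr(fit)
  ll <- logLik(fit)
  structure(
    list(beta = lme4::fixef(fit),
         sigma_s2 = as.numeric(vc[[subject]][1, 1]),
         sigma_e2 = attr(vc, "sc")^2,
         loglik = as.numeric(ll),
         n_par = attr(ll, "df"),
         n_obs = stats::nobs(fit),
         formula = formula,
         subject = subject,
         model = fit),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("<lmm_fit>", deparse(x$formula), sprintf("+ (1 | %s)", x$subject), "\n")
  cat(sprintf("  logLik %.3f (%d parameters, %d obs)\n",
              x$loglik, x$n_par, x$n_obs))
  cat(sprintf("  sigma_s^2 = %.4g, sigma_e^2 = %.4g\n",
              x$sigma_s2, x$sigma_e2))
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
tidy.lmm_fit <- function(x, ...) {
  se <- sqrt(diag(as.matrix(stats::vcov(x$model))))
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(se),
         statistic = unname(x$beta) / unname(se))
}

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n_par = x$n_par, n_obs = x$n_obs,
         sigma_s2 = x$sigma_s2, sigma_e2 = x$sigma_e2,
         AIC = -2 * x$loglik + 2 * x$n_par)
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' `chisq = 2 * (logLik(full) - logLik(reduced))` (clamped at zero), with
#' degrees of freedom equal to the parameter-count difference and the p
#' value from the upper chi-square tail.
#'
#' @param full,reduced `lmm_fit` objects on the same data, `reduced` nested
#'   in `full`.
#' @return A one-row tibble with `chisq`, `df` and `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$n_obs != reduced$n_obs) {
    abort("Models were fitted to different numbers of observations.")
  }
  df <- full$n_par - reduced$n_par
  if (df <= 0) {
    abort("`reduced` must be nested in `full` (fewer parameters).")
  }
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  tibble(chisq = chisq, df = df, p_value = pchisq(chisq, df, lower.tail = FALSE))
}

#' Proportional reduction in residual variance
#'
#' Effect size for a mixed-model comparison: the proportion by which the
#' full model reduces the reduced model's residual variance,
#' `(sigma_e2(reduced) - sigma_e2(full)) / sigma_e2(reduced)`, clamped to
#' `[0, 1]`.
#'
#' @param full,reduced `lmm_fit` objects on the same data.
#' @return A proportion in `[0, 1]`.
#' @export
effect_size <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (reduced$sigma_e2 <= 0) {
    abort("Reduced model has zero residual variance; effect size undefined.")
  }
  min(max((reduced$sigma_e2 - full$sigma_e2) / reduced$sigma_e2, 0), 1)
}

#' Pairwise Tukey contrasts with Holm correction
#'
#' All pairwise contrasts of the levels of a fixed factor in a
#' random-intercept model, with pooled standard errors from the fit, normal
#' (z) statistics and two-tailed p values, Holm-adjusted across the family.
#' The z reference (rather than studentized-range quantiles) matches the
#' convention of reporting `glht`-style z statistics for mixed models.
#'
#' @param fit an `lmm_fit` whose fixed part contains `factor_name` as a
#'   factor with at least three levels.
#' @param factor_name name of the factor to contrast.
#' @return A tibble with `contrast`, `estimate`, `std_error`, `z`,
#'   `p_value` (raw, two-tailed normal) and `p_holm`.
#' @export
tukey_posthoc <- function(fit, factor_name) {
  stopifnot(inherits(fit, "lmm_fit"))
  model_frame <- stats::model.frame(fit$model)
  if (!factor_name %in% names(model_frame)) {
    abort(sprintf("Factor '%s' is not in the fitted model.", factor_name))
  }
  if (!is.factor(model_frame[[factor_name]])) {
    abort(sprintf("'%s' must enter the model as a factor with at least 3 levels.",
                  factor_name))
  }
  lv <- levels(model_frame[[factor_name]])
  if (length(lv) < 3L) {
    abort("Tukey contrasts need a factor with at least 3 levels; use lrt().")
  }
  spec <- setNames(list("Tukey"), factor_name)
  gl <- multcomp::glht(fit$model, linfct = do.call(multcomp::mcp, spec))
  sm <- summary(gl, test = multcomp::adjusted("none"))
  est <- as.numeric(sm$test$coefficients)
  se <- as.numeric(sm$test$sigma)
  z <- est / se
  p_raw <- 2 * pnorm(-abs(z))
  tibble(contrast = names(sm$test$coefficients),
         estimate = est, std_error = se, z = z,
         p_value = p_raw, p_holm = holm_adjust(p_raw))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sorts the p values ascending, multiplies the i-th smallest by
#' `m - i + 1`, enforces monotonicity, caps at 1 and returns the adjusted
#' values in the original order.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
#'
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("All p values must lie in [0, 1].")
  }
  p.adjust(p, method = "holm")
}
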