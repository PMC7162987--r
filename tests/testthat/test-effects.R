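# Small balanced repeated-measures dataset generator.
lmm_data <- function(n_subj, k = 3, beta1 = 0, sigma_s = 1, sigma_e = 0.5,
                     seed = NULL, x = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subj <- rep(seq_len(n_subj), each = k)
  x <- x %||% rnorm(n_subj * k)
  tibble::tibble(
    subject_id = subj,
    x = x,
    y = 10 + beta1 * x + rep(rnorm(n_subj, 0, sigma_s), each = k) +
      rnorm(n_subj * k, 0, sigma_e)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

fake_fit <- function(loglik, n_par, sigma_e2 = 1, n_obs = 45) {
  structure(list(loglik = loglik, n_par = n_par, sigma_e2 = sigma_e2,
                 n_obs = n_obs), class = "lmm_fit")
}

test_that("ML fit collapses to OLS when between-subject spread is zero", {
  # with no true subject variance the ML variance estimate frequently hits
  # the boundary; whenever it does, the fixed effects are exactly OLS
  boundary <- 0L
  for (s in 1:10) {
    d <- lmm_data(30, sigma_s = 0, sigma_e = 1, beta1 = 2, seed = s)
    fit <- fit_lmm(d, y ~ x)
    expect_lt(fit$sigma_s2, 0.25)
    if (fit$sigma_s2 < 1e-8) {
      boundary <- boundary + 1L
      ols <- lm(y ~ x, data = d)
      expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
    }
  }
  expect_gte(boundary, 3L)
})

test_that("intercept-only ML estimate on balanced data is the grand mean", {
  d <- lmm_data(20, sigma_s = 1, sigma_e = 0.5, seed = 2)
  fit <- fit_lmm(d, y ~ 1)
  expect_equal(unname(fit$beta[1]), mean(d$y), tolerance = 1e-6)
  expect_true(is.finite(fit$loglik))
  expect_equal(fit$n_obs, 60L)
})

test_that("the fixed slope is recovered across replicates", {
  est <- vapply(1:100, function(i) {
    d <- lmm_data(50, beta1 = 2, sigma_s = 1, sigma_e = 0.5, seed = 100 + i)
    fit_lmm(d, y ~ x)$beta[["x"]]
  }, 1)
  expect_lt(abs(mean(est) - 2), 0.2)
})

test_that("tidy and glance expose the fit in broom style", {
  d <- lmm_data(15, beta1 = 1, seed = 3)
  fit <- fit_lmm(d, y ~ x)
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "x"))
  expect_true(all(c("estimate", "std.error", "statistic") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$loglik)
  expect_true(gl$sigma_e2 > 0)
})

test_that("the full model never has lower log-likelihood than a nested one", {
  for (i in 1:20) {
    d <- lmm_data(12, beta1 = 0.3 * (i %% 3), seed = 400 + i)
    full <- fit_lmm(d, y ~ x)
    red <- fit_lmm(d, y ~ 1)
    expect_gte(full$loglik, red$loglik - 1e-8)
  }
})

test_that("likelihood-ratio tests compare nested fits", {
  # equal log-likelihoods: chi-square 0, p = 1
  eq <- lrt(fake_fit(-10, 4), fake_fit(-10, 3))
  expect_equal(eq$chisq, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$df, 1)
  # clamped at zero even if the optimizer left the full fit marginally lower
  cl <- lrt(fake_fit(-10.001, 4), fake_fit(-10, 3))
  expect_equal(cl$chisq, 0)
  expect_error(lrt(fake_fit(-10, 3), fake_fit(-9, 3)), "nested")
  expect_error(lrt(fake_fit(-10, 4, n_obs = 30), fake_fit(-9, 3, n_obs = 45)),
               "different numbers")

  d <- lmm_data(25, beta1 = 3, sigma_e = 0.5, seed = 5)
  res <- lrt(fit_lmm(d, y ~ x), fit_lmm(d, y ~ 1))
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 1e-6)
})

test_that("a strong fixed effect is detected essentially always", {
  pvals <- vapply(1:200, function(i) {
    d <- lmm_data(15, beta1 = 2.5, sigma_s = 1, sigma_e = 0.5, seed = 600 + i)
    lrt(fit_lmm(d, y ~ x), fit_lmm(d, y ~ 1))$p_value
  }, 1)
  expect_gte(mean(pvals < 0.001), 0.95)
})

test_that("effect size is the proportional reduction in residual variance", {
  expect_equal(effect_size(fake_fit(-5, 4, sigma_e2 = 5),
                           fake_fit(-9, 3, sigma_e2 = 10)), 0.5)
  expect_equal(effect_size(fake_fit(-9, 4, sigma_e2 = 10),
                           fake_fit(-9, 3, sigma_e2 = 10)), 0)
  expect_error(effect_size(fake_fit(-5, 4), fake_fit(-9, 3, sigma_e2 = 0)),
               "zero residual")

  # recovery of a known variance split: slope beta1 on a balanced
  # within-subject predictor x = (-1, 0, 1). The reduced model's residual
  # picks up the within-subject x variation per degree of freedom,
  # sum(x - xbar)^2 / (k - 1) = beta1^2, so the true proportion is
  # (beta1^2 + sigma_e^2 - sigma_e^2) / (beta1^2 + sigma_e^2) = 0.5.
  props <- vapply(1:100, function(i) {
    set.seed(800 + i)
    x <- rep(c(-1, 0, 1), 40)
    d <- lmm_data(40, beta1 = 1, sigma_s = 1, sigma_e = 1, x = x)
    effect_size(fit_lmm(d, y ~ x), fit_lmm(d, y ~ 1))
  }, 1)
  expect_lt(abs(mean(props) - 0.5), 0.05)
})

test_that("Tukey contrasts report z statistics with Holm correction", {
  # three level means forced exactly equal: all z = 0, all p = 1
  d <- tibble::tibble(
    subject_id = rep(1:10, each = 3),
    task = factor(rep(c("a", "b", "c"), 10)),
    value = rep(rnorm(10), each = 3)
  )
  # degenerate zero-residual data can trip optimizer roundoff warnings
  ct <- suppressWarnings(tukey_posthoc(fit_lmm(d, value ~ task), "task"))
  expect_equal(nrow(ct), 3L)
  expect_true(all(abs(ct$z) < 1e-6))
  expect_true(all(ct$p_holm == 1))
  expect_true(all(ct$p_holm >= ct$p_value))

  # contrast antisymmetry under reversed level order
  set.seed(12)
  d2 <- tibble::tibble(
    subject_id = rep(1:12, each = 3),
    task = factor(rep(c("a", "b", "c"), 12)),
    value = rnorm(36) + rep(c(0, 1, 2), 12)
  )
  ct_ab <- tukey_posthoc(fit_lmm(d2, value ~ task), "task")
  d2$task <- factor(d2$task, levels = c("c", "b", "a"))
  ct_ba <- tukey_posthoc(fit_lmm(d2, value ~ task), "task")
  z1 <- ct_ab$z[ct_ab$contrast == "b - a"]
  z2 <- ct_ba$z[ct_ba$contrast == "a - b"]
  expect_equal(z1, -z2, tolerance = 1e-6)

  expect_error(tukey_posthoc(fit_lmm(lmm_data(10, seed = 1), y ~ x), "x"),
               "at least 3")
})

test_that("simulated adaptation-ordered data yields the right contrast signs", {
  hits <- vapply(1:200, function(i) {
    set.seed(900 + i)
    d <- tibble::tibble(
      subject_id = rep(1:15, each = 3),
      task = factor(rep(c("dAD", "nAD", "sAD"), 15)),
      value = rep(rnorm(15, 0, 5), each = 3) +
        rep(c(22, 34, 50), 15) + rnorm(45, 0, 8)
    )
    ct <- tukey_posthoc(fit_lmm(d, value ~ task), "task")
    all(ct$z[ct$contrast == "nAD - dAD"] > 0,
        ct$z[ct$contrast == "sAD - dAD"] > 0,
        ct$z[ct$contrast == "sAD - nAD"] > 0)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  set.seed(13)
  p <- runif(8)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= pmin(1, length(p) * p)))
  # permutation equivariance
  perm <- sample(8)
  expect_equal(holm_adjust(p[perm]), adj[perm])
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
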