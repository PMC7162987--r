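test_that("MAD screening flags gross outliers and only those", {
  x <- c(2, 4, 6, 8, 100)
  mask <- mad_outliers(x)
  expect_identical(mask, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # hand computation: median 6, scaled MAD 1.4826 * 2 = 2.9652,
  # score for 100 = 94 / 2.9652 = 31.7 > 2.5
  expect_gt(abs(100 - 6) / (1.4826 * 2), 2.5)

  expect_warning(none <- mad_outliers(rep(5, 6)), "MAD is zero")
  expect_false(any(none))

  # affine equivariance of median and MAD implies mask invariance
  y <- c(3, 9, 1, 50, 7, 6, 5)
  expect_identical(mad_outliers(-2 * y + 100), mad_outliers(y))
  expect_error(mad_outliers(c(1, 2)), "at least 3")
})

test_that("between-subject CV is the sample-SD to mean ratio in percent", {
  expect_equal(cv_between(c(10, 10, 10)), 0)
  expect_equal(cv_between(c(8, 12)), 100 * sqrt(8) / 10) # 28.28
  x <- c(3, 5, 9, 11)
  expect_equal(cv_between(7 * x), cv_between(x))
  expect_error(cv_between(c(-1, 1)), "mean is zero")
  expect_error(cv_between(5), "at least 2")
})

test_that("within-subject CV averages per-subject CVs over sessions", {
  m <- rbind(c(10, 10, 10), c(10, 20, 30))
  expect_equal(cv_within(m), mean(c(0, 100 * 10 / 20))) # 25
  expect_equal(cv_within(rbind(c(4, 4), c(9, 9))), 0)
  # permuting sessions within rows changes nothing
  expect_equal(cv_within(m[, c(3, 1, 2)]), cv_within(m))
  # definitional consistency with cv_between applied per row
  m2 <- matrix(rlnorm(30, 2, 0.3), 10, 3)
  expect_equal(cv_within(m2), mean(apply(m2, 1, cv_between)))
})

test_that("ICC(A,k) equals the brute-force ANOVA oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 10, 3), n, k) +
      rnorm(n, 0, sample(0:3, 1)) # random subject effects
    expect_equal(icc_avg_absolute(m), icc_oracle(m), tolerance = 1e-10)
  }
})

test_that("ICC limits, invariances and session-bias penalty behave as theory says", {
  # distinct constant rows: zero error variance -> ICC 1
  m <- matrix(rep(c(1, 5, 9, 13), 3), 4, 3)
  expect_equal(icc_avg_absolute(m), 1)

  set.seed(7)
  m <- matrix(rnorm(30, 20, 4), 10, 3) + rnorm(10, 0, 3)
  expect_equal(icc_avg_absolute(m + 100), icc_avg_absolute(m), tolerance = 1e-10)
  expect_equal(icc_avg_absolute(m * 3.7), icc_avg_absolute(m), tolerance = 1e-10)

  # absolute agreement penalizes a pure session shift
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 5
  expect_lt(icc_avg_absolute(shifted), icc_avg_absolute(m))

  expect_warning(flat <- icc_avg_absolute(matrix(3, 5, 3)), "zero total variance")
  expect_true(is.na(flat))

  # negative raw estimates are clamped only on request
  set.seed(8)
  noise <- matrix(rnorm(6, 0, 1), 3, 2)
  raw <- icc_avg_absolute(noise)
  expect_equal(icc_avg_absolute(noise, clamp = TRUE), min(max(raw, 0), 1))

  # incomplete subjects are dropped
  m_na <- m
  m_na[2, 3] <- NA
  expect_equal(icc_avg_absolute(m_na), icc_avg_absolute(m[-2, ]))
  expect_error(icc_avg_absolute(matrix(1:4, 4, 1)), "at least 2")
})

test_that("Bland-Altman pairs combine means with percentage differences", {
  ba <- bland_altman(c(10, 10), c(10, 20))
  expect_equal(ba$pair_mean, c(10, 15))
  expect_equal(ba$pct_diff, c(0, 100 * (10 - 20) / 15)) # -66.67
  # antisymmetry
  a <- c(4, 8, 15); b <- c(5, 7, 19)
  expect_equal(bland_altman(b, a)$pct_diff, -bland_altman(a, b)$pct_diff)
  expect_warning(z <- bland_altman(1, -1), "zero mean")
  expect_true(is.na(z$pct_diff))
  expect_error(bland_altman(1:3, 1:2), "equal length")
})

test_that("reliability_table assembles per-task rows with screening and ICC", {
  spec <- measure_spec("toy", c(10, 10, 10), c(3, 3, 3), cv_ws = 0)
  ds <- measures_dataset(spec, 12, seed = 21)
  row <- reliability_table(ds)
  expect_equal(nrow(row), 1L)
  expect_equal(row$cv_ws, 0, tolerance = 1e-9)
  expect_equal(row$icc, 1, tolerance = 1e-9)
  expect_equal(row$n_subjects, 12L)

  # session subset: ICC over Short1/Short2 only (k = 2)
  spec2 <- measure_spec("toy", c(10, 12, 14), c(3, 3, 3), cv_ws = 10)
  ds2 <- measures_dataset(spec2, 12, seed = 22)
  full <- reliability_table(ds2)
  sub <- reliability_table(ds2, icc_sessions = c("Short1", "Short2"))
  m <- matrix(ds2$value, 12)[, 1:2]
  expect_equal(sub$icc_raw, icc_avg_absolute(m), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(full$icc_raw, sub$icc_raw)))

  # row bookkeeping across multiple tasks and measures
  ds3 <- dplyr::bind_rows(
    measures_dataset(spec2, 8, seed = 1, task = "sDT"),
    measures_dataset(spec2, 8, seed = 2, task = "sRT", measure = "rt_median"),
    measures_dataset(spec2, 8, seed = 3, task = "sRT", measure = "rt_isv")
  )
  tab <- reliability_table(ds3)
  expect_equal(nrow(tab), 3L)
  expect_setequal(paste(tab$task, tab$measure),
                  c("sDT threshold", "sRT rt_median", "sRT rt_isv"))
})

test_that("outlier removal drops measurements, then incomplete subjects from the ICC", {
  spec <- measure_spec("toy", c(10, 10, 10), c(2, 2, 2), cv_ws = 5)
  ds <- measures_dataset(spec, 10, seed = 31) # no natural outliers at this draw
  ds$value[ds$subject_id == "S03" & ds$version == "Long"] <- 500 # gross outlier
  tab <- reliability_table(ds)
  expect_equal(tab$n_removed, 1L)
  expect_equal(tab$n_subjects, 9L) # S03 incomplete, dropped from ICC
  # per-session stats for the other versions still use S03
  kept <- ds$value[ds$version == "Short1"]
  expect_equal(tab$mean_Short1, mean(kept))
})
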