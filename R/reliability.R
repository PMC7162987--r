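#' Median-absolute-deviation outlier screen
#'
#' Flags observations whose distance from the median exceeds `threshold`
#' robust standard deviations, where the robust SD is the scaled median
#' absolute deviation (constant 1.4826). When the MAD is zero nothing is
#' flagged and a warning is issued.
#'
#' @param x numeric vector (length ≥ 3).
#' @param threshold robust z-score cutoff (default 2.5).
#' @return Logical vector; `TRUE` marks an outlier. `NA` entries are never
#'   flagged.
#' @export
#'
#' @examples
#' mad_outliers(c(2, 4, 6, 8, 100))
mad_outliers <- function(x, threshold = 2.5) {
  if (sum(!is.na(x)) < 3L) {
    abort("Need at least 3 non-missing values for MAD screening.")
  }
  med <- median(x, na.rm = TRUE)
  scaled_mad <- mad(x, na.rm = TRUE) # 1.4826 * MAD
  if (scaled_mad == 0) {
    warn("MAD is zero; no outliers flagged.")
    return(rep(FALSE, length(x)))
  }
  out <- abs(x - med) / scaled_mad > threshold
  out[is.na(out)] <- FALSE
  out
}

#' Between-subject coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n − 1) SD.
#'
#' @param values numeric vector (length ≥ 2, non-zero mean).
#' @return CV in percent.
#' @export
cv_between <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) abort("Need at least 2 values for a CV.")
  m <- mean(values)
  if (m == 0) abort("CV undefined: mean is zero.")
  100 * sd(values) / m
}

#' Within-subject coefficient of variation
#'
#' Mean over subjects of each subject's across-session CV (per-subject
#' sample SD over per-subject mean, times 100). Subjects with fewer than two
#' non-missing sessions are ignored.
#'
#' @param m numeric matrix, subjects in rows and sessions in columns.
#' @return CV in percent.
#' @export
cv_within <- function(m) {
  m <- as.matrix(m)
  per_subject <- apply(m, 1, function(row) {
    row <- row[!is.na(row)]
    if (length(row) < 2L) return(NA_real_)
    mu <- mean(row)
    if (mu == 0) abort("Within-subject CV undefined: a subject mean is zero.")
    100 * sd(row) / mu
  })
  per_subject <- per_subject[!is.na(per_subject)]
  if (length(per_subject) < 1L) {
    abort("Need at least one subject with two sessions for a within-subject CV.")
  }
  mean(per_subject)
}

#' Intraclass correlation: two-way, absolute agreement, average measures
#'
#' ICC(A,k) in the McGraw & Wong nomenclature, computed from the two-way
#' ANOVA mean squares with subjects as rows and sessions as columns:
#' `(MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)`, where `MS_R`, `MS_C` and
#' `MS_E` are the row, column and error mean squares and `n` the number of
#' subjects. This is the average-measures absolute-agreement form of the
#' two-way model: a pure session shift lowers it, unlike consistency forms.
#'
#' Subjects with any missing session are dropped before computation. The raw
#' estimate is returned (it can be negative or exceed 1 in small samples);
#' use `clamp = TRUE` to truncate to `[0, 1]` for reporting.
#'
#' @param m numeric matrix, subjects in rows and sessions in columns.
#' @param clamp truncate the estimate to `[0, 1]`?
#' @return The ICC estimate, or `NA` (with a warning) when the matrix has no
#'   variance at all.
#' @export
#'
#' @examples
#' m <- sample_measures(measure_spec("toy", c(10, 10, 10), c(3, 3, 3), 5),
#'                      n_subjects = 20, seed = 1)
#' icc_avg_absolute(m)
icc_avg_absolute <- function(m, clamp = FALSE) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) {
    abort("ICC needs a complete matrix with at least 2 subjects and 2 sessions.")
  }
  gm <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_r <- k * sum((row_means - gm)^2)
  ss_c <- n * sum((col_means - gm)^2)
  ss_e <- sum((m - outer(row_means, rep(1, k)) -
                 outer(rep(1, n), col_means) + gm)^2)
  if (ss_r + ss_c + ss_e < .Machine$double.eps * n * k) {
    warn("Matrix has zero total variance; ICC undefined.")
    return(NA_real_)
  }
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
  if (clamp) icc <- min(max(icc, 0), 1)
  icc
}

#' Bland-Altman agreement quantities
#'
#' For each pair of repeated measurements returns the pair mean
#' `(a + b) / 2` and the percentage difference `100 * (a - b) / mean`.
#' Pairs with zero mean yield `NA` with a warning.
#'
#' @param a,b numeric vectors of equal length (paired measurements).
#' @return A tibble with columns `pair_mean` and `pct_diff`.
#' @export
#'
#' @examples
#' bland_altman(c(10, 10), c(10, 20))
bland_altman <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  pm <- (a + b) / 2
  zero <- !is.na(pm) & pm == 0
  if (any(zero)) {
    warn(sprintf("%d pair(s) have zero mean; percentage difference undefined.",
                 sum(zero)))
  }
  pd <- ifelse(zero, NA_real_, 100 * (a - b) / pm)
  tibble(pair_mean = pm, pct_diff = pd)
}

#' Per-task reliability summary table
#'
#' Computes, for every `(task, measure)` pair in a tidy study dataset, the
#' full reliability row: MAD outlier screening collapsed over sessions,
#' per-session mean ± SD and between-subject CV, the pooled all-sessions
#' mean ± SD and CV, the within-subject CV, and the two-way
#' absolute-agreement average-measures ICC. Outlier screening removes
#' individual measurements; the ICC then drops subjects left with an
#' incomplete row, while CVs use all retained data.
#'
#' @param data tidy tibble with columns `subject_id`, `task`, `measure`,
#'   `value` and the session column named by `session_col`.
#' @param icc_sessions optional character vector restricting the ICC to a
#'   subset of session labels (e.g. `c("Short1", "Short2")`, in which case
#'   `k = 2` in the ICC).
#' @param mad_threshold MAD screening threshold (default 2.5).
#' @param session_col which column defines the ICC columns: `"version"`
#'   (Short1/Short2/Long; default) or `"session_index"` (chronological).
#' @return A tibble with one row per `(task, measure)`: per-session columns
#'   `mean_<s>`, `sd_<s>`, `cvbs_<s>`, pooled columns `mean_all`, `sd_all`,
#'   `cvbs_all`, then `cv_ws`, `icc` (clamped to `[0, 1]`), `icc_raw`,
#'   `n_subjects` (complete subjects entering the ICC) and `n_removed`
#'   (measurements removed as outliers).
#' @export
reliability_table <- function(data, icc_sessions = NULL, mad_threshold = 2.5,
                              session_col = c("version", "session_index")) {
  session_col <- match.arg(session_col)
  required <- c("subject_id", session_col, "task", "measure", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("Dataset is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  groups <- data %>% distinct(.data$task, .data$measure)
  rows <- purrr::pmap(groups, function(task, measure) {
    d <- data[data$task == task & data$measure == measure, ]
    if (nrow(d) == 0 || all(is.na(d$value))) {
      warn(sprintf("Task %s / %s has no data; skipped.", task, measure))
      return(NULL)
    }
    # outlier screen collapsed over all sessions
    keep <- rep(TRUE, nrow(d))
    if (sum(!is.na(d$value)) >= 3L) {
      keep <- !mad_outliers(d$value, mad_threshold)
    }
    n_removed <- sum(!keep)
    d <- d[keep, ]
    sessions <- sort(unique(as.character(d[[session_col]])))
    if (session_col == "version") {
      canonical <- c("Short1", "Short2", "Long")
      sessions <- c(intersect(canonical, sessions),
                    setdiff(sessions, canonical))
    }
    per_session <- lapply(sessions, function(s) {
      v <- d$value[as.character(d[[session_col]]) == s]
      v <- v[!is.na(v)]
      list(mean = mean(v), sd = if (length(v) >= 2) sd(v) else NA_real_,
           cvbs = if (length(v) >= 2 && mean(v) != 0) cv_between(v) else NA_real_)
    })
    names(per_session) <- sessions
    pooled <- d$value[!is.na(d$value)]
    # subject x session matrix on retained data
    wide <- d %>%
      mutate(session = as.character(.data[[session_col]])) %>%
      select("subject_id", "session", "value") %>%
      pivot_wider(names_from = "session", values_from = "value")
    mat <- as.matrix(wide[, sessions, drop = FALSE])
    rownames(mat) <- wide$subject_id
    cvw <- tryCatch(cv_within(mat), error = function(e) NA_real_)
    icc_mat <- mat
    if (!is.null(icc_sessions)) {
      icc_mat <- mat[, intersect(sessions, icc_sessions), drop = FALSE]
    }
    icc_mat <- icc_mat[stats::complete.cases(icc_mat), , drop = FALSE]
    icc_raw <- if (nrow(icc_mat) >= 2L && ncol(icc_mat) >= 2L) {
      tryCatch(suppressWarnings(icc_avg_absolute(icc_mat)),
               error = function(e) NA_real_)
    } else NA_real_
    out <- tibble(task = task, measure = measure)
    for (s in sessions) {
      out[[paste0("mean_", s)]] <- per_session[[s]]$mean
      out[[paste0("sd_", s)]] <- per_session[[s]]$sd
      out[[paste0("cvbs_", s)]] <- per_session[[s]]$cvbs
    }
    out$mean_all <- mean(pooled)
    out$sd_all <- if (length(pooled) >= 2) sd(pooled) else NA_real_
    out$cvbs_all <- if (length(pooled) >= 2) cv_between(pooled) else NA_real_
    out$cv_ws <- cvw
    out$icc <- if (is.na(icc_raw)) NA_real_ else min(max(icc_raw, 0), 1)
    out$icc_raw <- icc_raw
    out$n_subjects <- nrow(icc_mat)
    out$n_removed <- n_removed
    out
  })
  list_rbind(rows[!vapply(rows, is.null, TRUE)])
}
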