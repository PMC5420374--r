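#' Intraclass correlation ICC(2,1): single measures, absolute agreement
#'
#' Two-way random-effects ANOVA decomposition of a complete subjects x
#' raters matrix:
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' where `MSR`, `MSC`, `MSE` are the mean squares for rows (subjects),
#' columns (raters) and error. Absolute agreement: a constant rater
#' offset lowers the coefficient.
#'
#' @param data Numeric matrix or data frame, subjects in rows, raters in
#'   columns; no missing cells (no imputation is done).
#' @return An `icc_result` with `icc`, `n_subjects`, `k_raters` and the
#'   mean squares; `ci_lo`/`ci_hi` are `NA` until [bootstrap_icc_ci()]
#'   fills them.
#' @examples
#' icc_2_1(matrix(c(1, 2, 2, 3, 3, 4), 3, 2, byrow = TRUE))$icc  # 2/3
#' @export
icc_2_1 <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) abort("`data` must be numeric")
  if (anyNA(m)) abort("missing cells are not allowed (no imputation)")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3) abort("need at least 3 subjects")
  if (k < 2) abort("need at least 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom <= 0) {
    if (msr - mse == 0) 1 else 0
  } else {
    (msr - mse) / denom
  }
  structure(list(icc = icc, n_subjects = n, k_raters = k,
                 msr = msr, msc = msc, mse = mse,
                 ci_lo = NA_real_, ci_hi = NA_real_,
                 n_boot = NA_integer_, seed = NA_integer_),
            class = "icc_result")
}

#' Nonparametric bootstrap CI for ICC(2,1)
#'
#' Resamples subjects (rows) with replacement `B` times, recomputes the
#' ICC, and returns the 2.5/97.5 percentile interval. Seeded and
#' reproducible. Degenerate resamples (zero between-subject variance)
#' contribute their defined ICC value.
#'
#' @param data Subjects x raters matrix as in [icc_2_1()].
#' @param B Number of bootstrap resamples (default 2000, minimum 200).
#' @param seed Integer RNG seed.
#' @param conf_level Confidence level (default 0.95).
#' @return An `icc_result` with `ci_lo`, `ci_hi`, `n_boot` and `seed`
#'   filled in, plus the vector of resampled ICCs in `boot_icc`.
#' @export
bootstrap_icc_ci <- function(data, B = 2000, seed = 1, conf_level = 0.95) {
  if (B < 200) abort("use at least 200 bootstrap resamples")
  res <- icc_2_1(data)
  m <- as.matrix(data)
  n <- nrow(m)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      icc_2_1(m[idx, , drop = FALSE])$icc
    }, numeric(1))
  })
  alpha <- (1 - conf_level) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  res$ci_lo <- min(ci[1], res$icc)
  res$ci_hi <- max(ci[2], res$icc)
  res$n_boot <- as.integer(B)
  res$seed <- as.integer(seed)
  res$boot_icc <- boot
  res
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f (%d subjects, %d raters)\n",
              x$icc, x$n_subjects, x$k_raters))
  if (!is.na(x$ci_lo)) {
    cat(sprintf("  bootstrap 95%% CI [%.3f, %.3f] (B = %d, seed %d)\n",
                x$ci_lo, x$ci_hi, x$n_boot, x$seed))
  }
  invisible(x)
}

#' @export
tidy.icc_result <- function(x, ...) {
  tibble(icc = x$icc, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
         n_subjects = x$n_subjects, k_raters = x$k_raters,
         msr = x$msr, msc = x$msc, mse = x$mse)
}

#' @rdname icc_2_1
#' @param x An `icc_result` from [bootstrap_icc_ci()].
#' @param ... Ignored.
#' @export
autoplot.icc_result <- function(x, ...) {
  if (is.null(x$boot_icc)) abort("run bootstrap_icc_ci() first")
  df <- tibble(icc = x$boot_icc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = c(x$ci_lo, x$icc, x$ci_hi),
                        linetype = c(2, 1, 2)) +
    ggplot2::labs(x = "bootstrap ICC(2,1)", y = "resamples",
                  title = sprintf("ICC %.3f [%.3f, %.3f]", x$icc, x$ci_lo, x$ci_hi)) +
    ggplot2::theme_minimal()
}

#' Simulate a multi-rater measurement study
#'
#' Fast-mode rater reliability phantom: each subject has a true tunnel
#' diameter; each rater measures it with a rater-specific systematic
#' offset (`N(0, sigma_rater)`) plus independent measurement error
#' (`N(0, sigma_error)`). Mirrors an inter-rater study where several
#' observers segment the same scans.
#'
#' @param true_values Numeric vector of true diameters, one per subject
#'   (e.g. drawn from a cohort), or `n_subjects` to draw them from the
#'   pooled default tunnel mix.
#' @param k_raters Number of raters (default 3).
#' @param sigma_rater SD of rater systematic offsets, mm.
#' @param sigma_error SD of residual measurement error, mm.
#' @param seed Integer RNG seed.
#' @return Subjects x raters numeric matrix.
#' @export
simulate_rater_measurements <- function(true_values, k_raters = 3,
                                        sigma_rater = 0.1, sigma_error = 0.6,
                                        seed = 1) {
  with_seed(seed, {
    if (length(true_values) == 1 && true_values == round(true_values) &&
        true_values > 1) {
      p <- default_widening_params()
      pick <- sample.int(nrow(p), true_values, replace = TRUE)
      true_values <- rnorm(true_values, p$d0_mean[pick], p$d0_sd[pick])
    }
    n <- length(true_values)
    rater_off <- rnorm(k_raters, 0, sigma_rater)
    m <- outer(true_values, rep(1, k_raters)) +
      outer(rep(1, n), rater_off) +
      matrix(rnorm(n * k_raters, 0, sigma_error), n, k_raters)
    dimnames(m) <- list(sprintf("S%03d", seq_len(n)),
                        sprintf("rater%d", seq_len(k_raters)))
    m
  })
}
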