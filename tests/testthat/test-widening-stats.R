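test_that("widening records carry exact per-subject deltas", {
  meas <- tibble::tibble(
    subject = rep(c("S1", "S2"), each = 2),
    group = "SB", tunnel = "femur", level = "cylinder",
    timepoint = rep(c("year0", "year1"), 2),
    diameter_mm = c(8.0, 8.8, 9.0, 9.0)
  )
  w <- widening_table(meas)
  expect_equal(w$delta_mm, c(0.8, 0))
  expect_equal(w$delta_pct, c(10, 0))
  # internal consistency: pct * d0 / 100 == mm
  expect_equal(w$delta_pct * w$d0 / 100, w$delta_mm, tolerance = 1e-9)

  # unmatched pairs are rejected
  expect_error(widening_table(meas[-2, ]), "missing a timepoint")
})

test_that("simulated SB femoral widening averages about 17 percent", {
  p <- dplyr::filter(default_widening_params(), tunnel == "femur", group == "SB")
  coh <- generate_cohort(cohort_spec(n_sb = 1000, n_db = 2, params = p |>
    dplyr::bind_rows(dplyr::mutate(default_widening_params()[3, ], group = "DB")),
    seed = 31))
  w <- dplyr::filter(widening_table(coh), group == "SB", level == "cylinder")
  expect_equal(mean(w$delta_pct), 17, tolerance = 0.1)  # 10% relative band
})

test_that("paired t matches the hand-computed example and edge cases", {
  r <- paired_t(c(1, 2, 3))
  expect_equal(r$estimate, 2)
  expect_equal(r$t_stat, 3.4641016, tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 0.0741799, tolerance = 1e-6)

  sym <- paired_t(c(-1, 0, 1))
  expect_equal(sym$t_stat, 0)
  expect_equal(sym$p_value, 1)

  expect_error(paired_t(c(0, 0, 0)), "zero")
  expect_error(paired_t(c(2, 2, 2)), "constant")
  expect_error(paired_t(1), "at least 2")
})

test_that("widening at the study's SB femoral effect size is detected in essentially every cohort", {
  hits <- withr::with_seed(7, {
    mean(replicate(1000, paired_t(rnorm(22, 1.4, 0.9))$p_value < 0.001))
  })
  expect_gte(hits, 0.99)
})

test_that("Welch test matches the reference and reduces to Student when appropriate", {
  r <- welch_t(c(1.4, 1.0, 1.8, 1.2), c(0.5, 0.7, 0.3, 0.5))
  expect_equal(r$t_stat, 4.4903, tolerance = 1e-4)
  expect_equal(r$df, 4.3033, tolerance = 1e-4)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  # equal variances and sizes: Welch df equals the pooled df
  withr::with_seed(8, {
    a <- rnorm(10); b <- rnorm(10)
    b <- (b - mean(b)) / sd(b) * sd(a) + mean(b)  # force equal variance
  })
  expect_equal(welch_t(a, b)$df, 18, tolerance = 1e-9)
})

test_that("SB femur vs DB femoral AM parameters separate at the 0.001 level in most cohorts", {
  hits <- withr::with_seed(9, {
    mean(replicate(500, {
      welch_t(rnorm(22, 1.4, 0.9), rnorm(20, 0.5, 0.6))$p_value < 0.001
    }))
  })
  expect_gt(hits, 0.5)
})

test_that("ICC(2,1) matches the hand-worked ANOVA and its boundary behaviour", {
  m <- matrix(c(1, 2, 2, 3, 3, 4), 3, 2, byrow = TRUE)
  r <- icc_2_1(m)
  expect_equal(r$icc, 2 / 3, tolerance = 1e-12)
  expect_equal(r$msr, 2)
  expect_equal(r$msc, 1.5)
  expect_equal(r$mse, 0)

  ident <- icc_2_1(cbind(1:6, 1:6, 1:6))
  expect_equal(ident$icc, 1)

  # absolute agreement: a constant rater offset lowers the coefficient
  base <- vc_rater_matrix(n = 50, s_rater = 0, seed = 3)
  offset <- base
  offset[, 2] <- offset[, 2] + 1.5
  expect_lt(icc_2_1(offset)$icc, icc_2_1(base)$icc)
  expect_lte(icc_2_1(offset)$icc, 1)

  expect_error(icc_2_1(rbind(m, c(NA, 1))), "missing")
  expect_error(icc_2_1(m[1:2, ]), "at least 3")
  expect_error(icc_2_1(matrix(1:5)), "at least 2")
})

test_that("ICC recovers the analytic variance-component value", {
  # sigma2: subject 4, rater 0.25, error 0.75 -> ICC = 4 / 5
  iccs <- vapply(1:30, function(s) {
    icc_2_1(vc_rater_matrix(n = 200, k = 3, seed = s))$icc
  }, numeric(1))
  expect_equal(mean(iccs), 0.8, tolerance = 0.03 / 0.8)
})

test_that("bootstrap CIs are seeded, degenerate-safe and honestly calibrated", {
  ident <- cbind(1:8, 1:8)
  b0 <- bootstrap_icc_ci(ident, B = 200, seed = 1)
  expect_equal(c(b0$ci_lo, b0$ci_hi), c(1, 1))

  m <- simulate_rater_measurements(15, 3, seed = 4)
  b1 <- bootstrap_icc_ci(m, B = 500, seed = 9)
  b2 <- bootstrap_icc_ci(m, B = 500, seed = 9)
  expect_identical(b1$boot_icc, b2$boot_icc)
  expect_lte(b1$ci_lo, b1$icc)
  expect_gte(b1$ci_hi, b1$icc)

  expect_error(bootstrap_icc_ci(m, B = 50), "at least 200")
})

test_that("bootstrap CI coverage stays near nominal over simulated rater studies", {
  # true ICC of the default rater model with the pooled tunnel mix
  p <- default_widening_params()
  v_subj <- mean(p$d0_sd^2) + var(p$d0_mean) * (nrow(p) - 1) / nrow(p)
  true_icc <- v_subj / (v_subj + 0.1^2 + 0.6^2)
  cover <- mean(vapply(1:500, function(i) {
    m <- simulate_rater_measurements(15, 3, seed = 1000 + i)
    b <- bootstrap_icc_ci(m, B = 400, seed = i)
    b$ci_lo <= true_icc && true_icc <= b$ci_hi
  }, logical(1)))
  # percentile-bootstrap undercoverage at n = 15 is expected and tolerated
  expect_gte(cover, 0.90)
})

test_that("required sample size follows the noncentral-t oracle", {
  expect_lte(required_sample_size(0.5, 0.74), 20)
  expect_equal(required_sample_size(1, 1), 10)      # delta = sd
  expect_equal(required_sample_size(20, 1), 2)      # huge effect: t-test floor
  # internal consistency: returned n reaches the power, n - 1 does not
  n <- required_sample_size(0.5, 0.74)
  expect_gte(power_paired_t(n, 0.5, 0.74), 0.80)
  expect_lt(power_paired_t(n - 1, 0.5, 0.74), 0.80)
  # normal approximation is close
  expect_lte(abs(required_sample_size(0.5, 0.74, method = "normal") - n), 2)
  expect_error(required_sample_size(-1, 1), "delta")
})

test_that("ratio-of-means percentages reproduce the printed integers", {
  expect_equal(pct_widening_ratio_of_means(8.3, 1.4), 17)
  expect_equal(pct_widening_ratio_of_means(5.8, 0.8), 14)
})

test_that("cohort reports summarise exactly in the noise-free limit", {
  p0 <- default_widening_params()
  p0$d0_sd <- 0
  # tiny but nonzero widening spread so the t-test is defined
  p0$dw_sd <- 1e-6
  coh0 <- generate_cohort(cohort_spec(params = p0, seed = 2))
  rep0 <- cohort_report(coh0)
  cyl <- dplyr::filter(rep0$widening, level == "cylinder") |>
    dplyr::arrange(group, tunnel)
  ref <- dplyr::arrange(p0, group, tunnel)
  expect_equal(cyl$year1_mean - cyl$year0_mean, ref$dw_mean, tolerance = 1e-4)
})

test_that("the seeded default cohort reproduces the qualitative widening pattern", {
  rep <- cohort_report(generate_cohort(cohort_spec(seed = 1)))
  # every tunnel widens significantly at the default effect sizes
  expect_true(all(rep$widening$p_value < 0.05))
  expect_true(all(rep$widening$widening_mm > 0))
  # SB femur vs DB femoral AM is the strongest group contrast
  cmp <- dplyr::filter(rep$comparison, level == "cylinder")
  expect_lt(cmp$p_value[cmp$tunnel_db == "femur_AM"], 0.05)
})

test_that("report tables round-trip through CSV without precision loss", {
  rep <- cohort_report(generate_cohort(cohort_spec(seed = 13)))
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(rep$widening), f, row.names = FALSE)
  back <- utils::read.csv(f)
  expect_equal(back$widening_mm, rep$widening$widening_mm, tolerance = 1e-12)
  expect_equal(back$p_value, rep$widening$p_value, tolerance = 1e-12)
})
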