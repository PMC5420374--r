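#' Power of a paired-difference t-test
#'
#' Exact power of the two-sided one-sample t-test on paired differences,
#' via the noncentral t distribution: with `n` pairs, true mean difference
#' `delta` and SD `sd`, the noncentrality is `delta / (sd / sqrt(n))` and
#' power is the probability that |t| exceeds the alpha/2 critical value.
#'
#' @param n Number of pairs (>= 2).
#' @param delta True mean difference, mm.
#' @param sd SD of the differences, mm.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
power_paired_t <- function(n, delta, sd, alpha = 0.05) {
  stopifnot(n >= 2, sd > 0, alpha > 0, alpha < 1)
  df <- n - 1
  tc <- qt(1 - alpha / 2, df)
  ncp <- delta / (sd / sqrt(n))
  1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
}

#' A priori sample size for detecting tunnel widening
#'
#' Smallest number of patients for which a two-sided paired-difference
#' t-test at level `alpha` reaches the target power for a true mean
#' widening `delta` with SD `sd`, found by iterating `n` over the exact
#' noncentral-t power ([power_paired_t()]). A normal-approximation
#' variant (`method = "normal"`) is provided for cross-checking.
#'
#' @param delta Detectable mean difference, mm (> 0).
#' @param sd SD of the paired differences, mm (> 0).
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param method `"nct"` (exact, default) or `"normal"`.
#' @param n_max Search bound (default 1e5).
#' @return Minimal integer `n` (at least 2).
#' @examples
#' required_sample_size(delta = 0.5, sd = 0.74)  # 20 patients
#' @export
required_sample_size <- function(delta, sd, alpha = 0.05, power = 0.80,
                                 method = c("nct", "normal"), n_max = 1e5) {
  method <- match.arg(method)
  stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (method == "normal") {
    za <- stats::qnorm(1 - alpha / 2)
    zb <- stats::qnorm(power)
    return(max(2L, as.integer(ceiling(((za + zb) * sd / delta)^2))))
  }
  for (n in 2:n_max) {
    if (power_paired_t(n, delta, sd, alpha) >= power) return(as.integer(n))
  }
  abort("no n below `n_max` reaches the requested power")
}
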