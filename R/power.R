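# Power for two-sample MR with a binary outcome, and the minimally
# detectable odds ratio at a target power.

check_power_args <- function(n_total, r2_gx, case_fraction, alpha, power_target = 0.8) {
  if (n_total < 1) mr_abort("n_total must be >= 1", "mrkit_config_error")
  for (v in c(r2_gx = r2_gx, case_fraction = case_fraction, alpha = alpha,
              power_target = power_target)) {
    if (!is.finite(v) || v <= 0 || v >= 1) {
      mr_abort("r2_gx, case_fraction, alpha and power_target must lie in (0, 1)",
               "mrkit_config_error")
    }
  }
  invisible(TRUE)
}

#' Power to detect a causal odds ratio
#'
#' Binary-outcome two-sample MR approximation: the test statistic has
#' noncentrality `z = |ln OR| * sqrt(n_total * r2_gx * K * (1 - K))` with
#' `K` the outcome case fraction, and power is `Phi(z - z_{1-alpha/2})`
#' (the upper-tail term of the two-sided test, the form used by the
#' standard MR power calculators; at OR = 1 it returns `alpha/2`, the size
#' contributed by that tail).
#'
#' @param or Causal odds ratio (vectorised).
#' @param n_total Outcome GWAS sample size.
#' @param r2_gx Variance in the exposure explained by the instruments.
#' @param case_fraction Outcome case fraction K in (0, 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1).
#' @export
mr_power <- function(or, n_total, r2_gx, case_fraction, alpha = 0.05) {
  check_power_args(n_total, r2_gx, case_fraction, alpha)
  z <- abs(log(or)) * sqrt(n_total * r2_gx * case_fraction * (1 - case_fraction))
  stats::pnorm(z - stats::qnorm(1 - alpha / 2))
}

#' Minimally detectable odds ratio at a target power
#'
#' Solves `mr_power(OR) = power_target` for OR > 1 by monotone root-finding
#' on the log-odds-ratio scale. The return value is at full precision (the
#' print convention is 3 significant figures), so
#' `mr_power(min_detectable_or(...))` round-trips to the target power.
#'
#' @inheritParams mr_power
#' @param power_target Target power (default 0.80).
#' @return The odds ratio detectable at the target power.
#' @export
min_detectable_or <- function(n_total, r2_gx, case_fraction, alpha = 0.05,
                              power_target = 0.80) {
  check_power_args(n_total, r2_gx, case_fraction, alpha, power_target)
  f <- function(l) {
    mr_power(exp(l), n_total, r2_gx, case_fraction, alpha) - power_target
  }
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  root <- stats::uniroot(f, c(1e-12, upper), tol = 1e-14)$root
  exp(root)
}
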