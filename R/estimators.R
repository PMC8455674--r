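# Causal estimators on a harmonized instrument set: Wald ratio, IVW with
# multiplicative random effects, Cochran's Q, weighted median, MR-Egger.

new_mr_estimate <- function(method, estimate, se, n_snp, extra = list()) {
  z <- estimate / se
  out <- c(list(method = method, estimate = estimate, std_error = se,
                conf_low = estimate - stats::qnorm(0.975) * se,
                conf_high = estimate + stats::qnorm(0.975) * se,
                p_value = 2 * stats::pnorm(-abs(z)),
                n_snp = as.integer(n_snp)),
           extra)
  class(out) <- c(paste0("mr_", method), "mr_estimate")
  out
}

check_set <- function(dat, min_snps, method) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  if (!all(need %in% names(dat))) {
    mr_abort("expected a harmonized set with beta/se columns for both traits",
             "mrkit_input_error")
  }
  if (nrow(dat) < min_snps) {
    mr_abort(paste0(method, " requires at least ", min_snps, " instruments (got ",
                    nrow(dat), ")"), "mrkit_estimation_error")
  }
  if (any(dat$se_exposure <= 0) || any(dat$se_outcome <= 0)) {
    mr_abort("standard errors must be positive", "mrkit_input_error")
  }
  invisible(dat)
}

#' Per-variant Wald ratio estimates
#'
#' The ratio of the variant-outcome to the variant-exposure association,
#' with the first-order standard error `se_outcome / |beta_exposure|`.
#'
#' @param dat Harmonized set (or data frame with the four beta/se columns).
#' @return Tibble with columns `rsid` (if available), `estimate`, `std_error`.
#' @export
wald_ratio <- function(dat) {
  check_set(dat, 1, "wald_ratio")
  if (any(dat$beta_exposure == 0)) {
    mr_abort("degenerate instrument: beta_exposure is exactly 0", "mrkit_estimation_error")
  }
  tibble::tibble(
    rsid = dat$rsid %||% as.character(seq_len(nrow(dat))),
    estimate = dat$beta_outcome / dat$beta_exposure,
    std_error = dat$se_outcome / abs(dat$beta_exposure)
  )
}

ivw_point <- function(g, G, sy) {
  w <- 1 / sy^2
  sum(g * G * w) / sum(g^2 * w)
}

#' Inverse-variance-weighted estimate with multiplicative random effects
#'
#' Pools per-variant Wald ratios by weighted regression of the outcome on
#' the exposure associations through the origin with weights
#' `1/se_outcome^2`. The multiplicative random-effects model scales the
#' fixed-effect variance by the residual overdispersion `Q/(J-1)`, floored
#' at 1 so the standard error never shrinks below the fixed-effect one.
#' Cochran's Q and its chi-square p-value (J-1 df) are attached. A single
#' instrument degrades to the Wald ratio with a warning.
#'
#' @param dat An `mr_harmonized` set.
#' @return An `mr_estimate` (`method = "ivw"`) with `q_stat`, `q_df`,
#'   `q_pvalue` and the overdispersion `phi2`.
#' @export
mr_ivw <- function(dat) {
  check_set(dat, 1, "mr_ivw")
  J <- nrow(dat)
  if (J == 1) {
    rlang::warn("single instrument: IVW degrades to the Wald ratio")
    w <- wald_ratio(dat)
    return(new_mr_estimate("ivw", w$estimate, w$std_error, 1,
                           list(q_stat = NA_real_, q_df = NA_integer_,
                                q_pvalue = NA_real_, phi2 = NA_real_)))
  }
  g <- dat$beta_exposure; G <- dat$beta_outcome; sy <- dat$se_outcome
  w <- 1 / sy^2
  denom <- sum(g^2 * w)
  beta <- sum(g * G * w) / denom
  q <- cochran_q(dat, beta)
  phi2 <- q$q_stat / (J - 1)
  se <- sqrt(max(1, phi2) / denom)
  new_mr_estimate("ivw", beta, se, J,
                  list(q_stat = q$q_stat, q_df = q$q_df, q_pvalue = q$q_pvalue,
                       phi2 = phi2))
}

#' Cochran's Q heterogeneity statistic
#'
#' Q = sum of w_j (ratio_j - beta)^2 over instruments, with first-order
#' ratio weights w_j = beta_exposure^2 / se_outcome^2, referred to a
#' chi-square with J - 1 degrees of freedom.
#'
#' @param dat An `mr_harmonized` set (J >= 2).
#' @param beta Pooled causal estimate around which heterogeneity is measured.
#' @return List with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(dat, beta) {
  check_set(dat, 2, "cochran_q")
  ratios <- dat$beta_outcome / dat$beta_exposure
  w <- dat$beta_exposure^2 / dat$se_outcome^2
  q <- sum(w * (ratios - beta)^2)
  df <- nrow(dat) - 1L
  list(q_stat = q, q_df = df, q_pvalue = stats::pchisq(q, df, lower.tail = FALSE))
}

# interpolated weighted median of b with weights w (normalised internally)
weighted_median_interp <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' Consistent when at least half the weight comes from valid instruments.
#' Per-variant Wald ratios are ordered and the weighted median is taken by
#' linear interpolation of the cumulative-weight midpoints at 0.5, with
#' first-order inverse-variance weights `beta_exposure^2 / se_outcome^2`.
#' The standard error comes from a seeded parametric bootstrap that redraws
#' both association estimates from normal distributions centred at the
#' observed values.
#'
#' @param dat An `mr_harmonized` set (J >= 3).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (required, for
#'   reproducibility; applied locally without disturbing the global RNG).
#' @return An `mr_estimate` (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed) {
  check_set(dat, 3, "mr_weighted_median")
  if (missing(seed)) mr_abort("seed is required for the bootstrap", "mrkit_config_error")
  J <- nrow(dat)
  g <- dat$beta_exposure; G <- dat$beta_outcome
  sx <- dat$se_exposure; sy <- dat$se_outcome
  est <- weighted_median_interp(G / g, g^2 / sy^2)
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      gb <- stats::rnorm(J, g, sx)
      Gb <- stats::rnorm(J, G, sy)
      weighted_median_interp(Gb / gb, gb^2 / sy^2)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  new_mr_estimate("weighted_median", est, se, J,
                  list(n_boot = as.integer(n_boot), seed = as.integer(seed)))
}

# weighted least squares y ~ [1,] x with weights w; returns coef, vcov
# scaled by max(1, residual chi2 / df) (multiplicative overdispersion)
wls_overdispersed <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  XtWX <- crossprod(X * sqrt(w))
  if (abs(det(XtWX)) < 1e-300 || (intercept && stats::sd(x) == 0)) {
    mr_abort("zero variance in exposure associations: collinear design",
             "mrkit_estimation_error")
  }
  XtWXinv <- solve(XtWX)
  coef <- unname(drop(XtWXinv %*% crossprod(X, w * y)))
  res <- y - drop(X %*% coef)
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * res^2) / df
  list(coef = coef, vcov = XtWXinv * max(1, sigma2), sigma2 = sigma2, df = df)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with a free intercept, after orienting every instrument so
#' its exposure association is non-negative. The slope is the causal
#' estimate (consistent under the InSIDE assumption even when all
#' instruments are pleiotropic); the intercept estimates the average
#' directional pleiotropy, with an intercept p-value below 0.05 indicating
#' its presence. Standard errors use weights `1/se_outcome^2` with
#' multiplicative overdispersion floored at 1. The I2(GX) statistic
#' quantifies relative measurement error in the exposure associations: a
#' high value supports the no-measurement-error assumption; the raw value
#' can be negative and is reported clipped at 0 alongside the raw value.
#'
#' @param dat An `mr_harmonized` set (J >= 3).
#' @param intercept Fit the intercept (default `TRUE`). With
#'   `intercept = FALSE` the fit is the origin-constrained weighted
#'   regression and the slope reproduces the IVW estimate.
#' @return An `mr_estimate` (`method = "egger"`) with `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_pvalue`, `i2_gx`, `i2_gx_raw`.
#' @export
mr_egger <- function(dat, intercept = TRUE) {
  check_set(dat, 3, "mr_egger")
  J <- nrow(dat)
  flip <- sign(dat$beta_exposure)
  flip[flip == 0] <- 1
  x <- dat$beta_exposure * flip
  y <- dat$beta_outcome * flip
  w <- 1 / dat$se_outcome^2
  fit <- wls_overdispersed(x, y, w, intercept = intercept)
  if (intercept) {
    b0 <- fit$coef[1]; b1 <- fit$coef[2]
    se0 <- sqrt(fit$vcov[1, 1]); se1 <- sqrt(fit$vcov[2, 2])
  } else {
    b0 <- NA_real_; se0 <- NA_real_
    b1 <- fit$coef[1]; se1 <- sqrt(fit$vcov[1, 1])
  }
  wx <- 1 / dat$se_exposure^2
  gbar <- sum(wx * x) / sum(wx)
  q_gx <- sum((x - gbar)^2 / dat$se_exposure^2)
  i2_raw <- (q_gx - (J - 1)) / q_gx
  new_mr_estimate("egger", b1, se1, J, list(
    egger_intercept = unname(b0), egger_intercept_se = unname(se0),
    egger_intercept_pvalue = if (intercept) 2 * stats::pnorm(-abs(b0 / se0)) else NA_real_,
    i2_gx = max(0, i2_raw), i2_gx_raw = i2_raw,
    phi2 = fit$sigma2
  ))
}

#' Run the full estimator battery on a harmonized set
#'
#' Runs IVW (multiplicative random effects), weighted median, MR-Egger and
#' MR-PRESSO; estimators whose minimum instrument count is not met are
#' reported as not applicable rather than failing. For binary outcomes the
#' tidied battery reports odds ratios (exponentiated); continuous outcomes
#' stay on the mean-difference scale.
#'
#' @param dat An `mr_harmonized` set.
#' @param trait_type `"binary"` or `"continuous"` outcome.
#' @param config An [mr_config()] (bootstrap / simulation counts, alpha).
#' @param seed Integer seed driving the weighted-median bootstrap and the
#'   MR-PRESSO simulations.
#' @return An `mr_battery` object; use [tidy()] for the results table.
#' @export
mr_estimate_all <- function(dat, trait_type = c("binary", "continuous"),
                            config = mr_config(), seed = 1L) {
  trait_type <- match.arg(trait_type)
  check_set(dat, 1, "mr_estimate_all")
  seed <- as.integer(seed)
  run <- function(min_j, fn) {
    if (nrow(dat) < min_j) return(NULL)
    fn()
  }
  est <- list(
    ivw = run(1, function() mr_ivw(dat)),
    weighted_median = run(3, function() mr_weighted_median(dat, n_boot = config$n_boot,
                                                           seed = seed)),
    egger = run(3, function() mr_egger(dat))
  )
  presso <- if (nrow(dat) >= 4) {
    mr_presso(dat, n_sim = config$n_sim, seed = seed + 1L, alpha = config$alpha)
  } else NULL
  structure(list(estimates = est, presso = presso, trait_type = trait_type,
                 n_snp = nrow(dat)),
            class = "mr_battery")
}
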