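test_that("Wald ratios follow the ratio and first-order SE definitions", {
  w <- wald_ratio(make_hset(0.1, 0.01, 0.2, 0.05))
  expect_equal(w$estimate, 2.0)
  expect_equal(w$std_error, 0.5)
  expect_equal(wald_ratio(make_hset(0.1, 0.01, 0, 0.05))$estimate, 0)
  expect_error(wald_ratio(make_hset(0, 0.01, 0.1, 0.05)),
               class = "mrkit_estimation_error")
})

test_that("IVW pools Wald ratios with multiplicative random effects", {
  # single instrument degrades to the Wald ratio with a warning
  one <- make_hset(0.1, 0.01, 0.2, 0.05)
  expect_warning(est1 <- mr_ivw(one), "single instrument")
  expect_equal(est1$estimate, 2.0)
  expect_equal(est1$std_error, 0.5)

  # two identical-gamma instruments: estimate is the midpoint ratio, Q > 0
  two <- make_hset(c(0.1, 0.1), c(0.01, 0.01), c(0.1, 0.3), c(0.05, 0.05))
  est2 <- mr_ivw(two)
  expect_equal(est2$estimate, 2.0)  # midpoint of ratios 1 and 3
  expect_gt(est2$q_stat, 0)

  # homogeneity: when Q <= J - 1 the SE equals the fixed-effect SE
  exact <- make_hset(c(0.1, 0.2, 0.3), rep(0.01, 3),
                     c(0.03, 0.06, 0.09), rep(0.05, 3))
  est3 <- mr_ivw(exact)
  expect_equal(est3$estimate, 0.3)
  expect_equal(est3$q_stat, 0, tolerance = 1e-20)
  fixed_se <- sqrt(1 / sum(exact$beta_exposure^2 / exact$se_outcome^2))
  expect_equal(est3$std_error, fixed_se)
})

test_that("IVW matches the independent origin-constrained WLS oracle", {
  for (seed in 1:20) {
    dat <- random_hset(sample(2:50, 1), seed = seed)
    expect_equal(mr_ivw(dat)$estimate, ivw_oracle(dat), tolerance = 1e-10)
  }
})

test_that("IVW is invariant to instrument order and consistent sign flips", {
  dat <- random_hset(20, seed = 31)
  est <- mr_ivw(dat)
  shuffled <- dat[withr::with_seed(1, sample(nrow(dat))), ]
  expect_equal(mr_ivw(shuffled)$estimate, est$estimate, tolerance = 1e-14)
  expect_equal(mr_ivw(shuffled)$std_error, est$std_error, tolerance = 1e-14)
  flipped <- dat
  flipped$beta_exposure <- -flipped$beta_exposure
  flipped$beta_outcome <- -flipped$beta_outcome
  expect_equal(mr_ivw(flipped)$estimate, est$estimate, tolerance = 1e-14)
})

test_that("Cochran's Q matches its term-by-term definition", {
  # all ratios identical: Q = 0, p = 1
  exact <- make_hset(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.10), c(0.04, 0.04))
  q0 <- cochran_q(exact, 0.5)
  expect_equal(q0$q_stat, 0, tolerance = 1e-24)
  expect_equal(q0$q_pvalue, 1)

  # J = 2 equal-weight symmetric case: Q = 2 * weight * half-gap^2
  sym <- make_hset(c(0.1, 0.1), c(0.01, 0.01), c(0.1, 0.3), c(0.05, 0.05))
  w <- 0.1^2 / 0.05^2
  expect_equal(cochran_q(sym, 2)$q_stat, 2 * w * 1^2)

  # a planted 10-sigma-discordant instrument dominates Q
  dat <- random_hset(15, seed = 7)
  beta <- mr_ivw(dat)$estimate
  dat$beta_outcome[1] <- dat$beta_exposure[1] * beta + 10 * dat$se_outcome[1]
  q <- cochran_q(dat, mr_ivw(dat)$estimate)
  terms <- with(dat, beta_exposure^2 / se_outcome^2 *
                       (beta_outcome / beta_exposure - mr_ivw(dat)$estimate)^2)
  expect_equal(q$q_stat, sum(terms), tolerance = 1e-12)
  expect_gt(terms[1] / q$q_stat, 0.5)
})

test_that("weighted median interpolates the cumulative-midpoint definition", {
  # equal weights, ratios {1, 2, 9} -> 2
  dat <- make_hset(c(0.1, 0.1, 0.1), rep(0.01, 3),
                   c(0.1, 0.2, 0.9), rep(0.05, 3))
  est <- mr_weighted_median(dat, n_boot = 50, seed = 1)
  expect_equal(est$estimate, 2)

  # a dominant instrument (> 50% of weight) pins the estimate near its ratio
  dom <- make_hset(c(1, 0.05, 0.05), c(0.01, 0.01, 0.01),
                   c(0.5, 0.2, 0.4), c(0.05, 0.05, 0.05))
  estd <- mr_weighted_median(dom, n_boot = 50, seed = 1)
  expect_lt(abs(estd$estimate - 0.5), 0.1)

  # equal weights reproduce the interpolated unweighted median
  eq <- make_hset(rep(0.1, 6), rep(0.01, 6),
                  c(0.11, 0.15, 0.22, 0.30, 0.05, 0.41), rep(0.05, 6))
  este <- mr_weighted_median(eq, n_boot = 50, seed = 1)
  expect_equal(este$estimate, wm_oracle(eq$beta_outcome / eq$beta_exposure,
                                        rep(1, 6)))
  expect_error(mr_weighted_median(dat[1:2, ], n_boot = 10, seed = 1),
               class = "mrkit_estimation_error")
})

test_that("weighted median matches the brute-force weighted-quantile oracle", {
  for (seed in 1:20) {
    dat <- random_hset(sample(3:30, 1), seed = 100 + seed)
    est <- mr_weighted_median(dat, n_boot = 10, seed = 1)
    oracle <- wm_oracle(dat$beta_outcome / dat$beta_exposure,
                        dat$beta_exposure^2 / dat$se_outcome^2)
    expect_equal(est$estimate, oracle, tolerance = 1e-12)
  }
})

test_that("MR-Egger recovers exact linear structure and its diagnostics", {
  g <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  dat <- make_hset(g, rep(0.01, 5), 0.3 * g, rep(0.05, 5))
  est <- mr_egger(dat)
  expect_equal(est$estimate, 0.3, tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0, tolerance = 1e-12)

  dat2 <- make_hset(g, rep(0.01, 5), 0.05 + 0.3 * g, rep(0.05, 5))
  est2 <- mr_egger(dat2)
  expect_equal(est2$egger_intercept, 0.05, tolerance = 1e-12)
  expect_equal(est2$estimate, 0.3, tolerance = 1e-12)
  expect_lte(est2$i2_gx, 1)
  expect_gte(est2$i2_gx, 0)

  # zero spread in the exposure associations is a collinearity error
  flat <- make_hset(rep(0.1, 4), rep(0.01, 4), c(0.1, 0.2, 0.15, 0.12), rep(0.05, 4))
  expect_error(mr_egger(flat), class = "mrkit_estimation_error")
})

test_that("Egger with the intercept constrained to zero reproduces IVW", {
  for (seed in 1:10) {
    dat <- random_hset(sample(3:40, 1), seed = 200 + seed)
    expect_equal(mr_egger(dat, intercept = FALSE)$estimate,
                 mr_ivw(dat)$estimate, tolerance = 1e-12)
  }
})

test_that("the battery gates estimators on instrument count and reports the right scale", {
  two <- random_hset(2, seed = 3)
  bat <- mr_estimate_all(two, "binary", mr_config(n_boot = 10, n_sim = 50), seed = 1)
  rows <- tidy(bat)
  expect_equal(rows$method, "ivw")  # WM/Egger/PRESSO not applicable at J = 2
  expect_null(bat$estimates$egger)

  dat <- random_hset(12, seed = 4)
  batb <- mr_estimate_all(dat, "binary", mr_config(n_boot = 20, n_sim = 100), seed = 1)
  rb <- tidy(batb)
  expect_equal(rb$estimate_exp, exp(rb$estimate))  # OR scale for binary
  batc <- mr_estimate_all(dat, "continuous", mr_config(n_boot = 20, n_sim = 100), seed = 1)
  expect_true(all(tidy(batc)$scale == "mean_difference"))
  expect_true(all(is.na(tidy(batc)$estimate_exp)))
})

test_that("estimate CIs bracket the estimate and SEs are positive", {
  dat <- random_hset(15, seed = 9)
  for (est in list(mr_ivw(dat), mr_weighted_median(dat, n_boot = 30, seed = 2),
                   mr_egger(dat))) {
    expect_lte(est$conf_low, est$estimate)
    expect_gte(est$conf_high, est$estimate)
    expect_gt(est$std_error, 0)
    if (!is.null(est$q_stat)) expect_gte(est$q_stat, 0)
  }
})
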