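# shared builders: all fixtures are constructed in code

# minimal harmonized-set tibble accepted by the estimators
make_hset <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                      rsid = sprintf("rs%d", seq_along(beta_exposure))) {
  tibble::tibble(
    rsid = rsid, proxy = NA_character_,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    eaf_exposure = NA_real_,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    eaf_outcome = NA_real_, action = "kept"
  )
}

# random harmonized instance for oracle comparisons
random_hset <- function(J, seed) {
  withr::with_seed(seed, {
    g <- runif(J, 0.02, 0.3) * sample(c(-1, 1), J, replace = TRUE)
    make_hset(
      beta_exposure = g,
      se_exposure = runif(J, 0.002, 0.02),
      beta_outcome = 0.2 * g + rnorm(J, 0, 0.05),
      se_outcome = runif(J, 0.01, 0.08)
    )
  })
}

# one-variant association row for harmonization fixtures
assoc_row <- function(rsid, ea, oa, beta, se = 0.01, eaf = NA_real_,
                      pvalue = 2 * pnorm(-abs(beta / se))) {
  tibble::tibble(rsid = rsid, effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se, pvalue = pvalue)
}

# independent origin-constrained weighted-least-squares oracle (normal
# equations via lm, a different route than the package's explicit sums)
ivw_oracle <- function(dat) {
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = dat,
            weights = 1 / dat$se_outcome^2)
  unname(coef(fit)[1])
}

# brute-force interpolated weighted-quantile oracle: direct scan of the
# cumulative-midpoint definition
wm_oracle <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  for (j in 2:length(b)) {
    if (s[j] >= 0.5) {
      return(b[j - 1] + (b[j] - b[j - 1]) * (0.5 - s[j - 1]) / (s[j] - s[j - 1]))
    }
  }
  b[length(b)]
}

write_gwas_file <- function(df, path, delim = "\t") {
  readr::write_delim(df, path, delim = delim)
  path
}
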