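test_that("non-palindromic alleles align directly, by swap, and by strand complement", {
  exposure <- dplyr::bind_rows(
    assoc_row("rs1", "A", "G", 0.10, eaf = 0.3),
    assoc_row("rs2", "A", "G", 0.10, eaf = 0.3),
    assoc_row("rs3", "A", "G", 0.10, eaf = 0.3),
    assoc_row("rs4", "A", "G", 0.10, eaf = 0.3)
  )
  outcome <- gwas_table(dplyr::bind_rows(
    assoc_row("rs1", "A", "G", 0.20, eaf = 0.31),   # direct
    assoc_row("rs2", "G", "A", 0.10, eaf = 0.69),   # swapped
    assoc_row("rs3", "T", "C", 0.20, eaf = 0.31),   # strand complement
    assoc_row("rs4", "C", "T", 0.10, eaf = 0.69)    # complement + swap
  ), "out", "binary")
  h <- harmonize(exposure, outcome)
  expect_equal(h$beta_outcome, c(0.20, -0.10, 0.20, -0.10))
  expect_equal(h$eaf_outcome, c(0.31, 0.31, 0.31, 0.31))
  expect_equal(h$action, c("kept", "allele_flipped", "kept", "allele_flipped"))
})

test_that("palindromes follow the frequency rule with the 0.42 MAF gate", {
  exposure <- dplyr::bind_rows(
    assoc_row("rs1", "A", "T", 0.10, eaf = 0.30),  # aligned, concordant
    assoc_row("rs2", "A", "T", 0.10, eaf = 0.45),  # MAF 0.45 > 0.42 -> drop
    assoc_row("rs3", "C", "G", 0.10, eaf = 0.30),  # discordant frequency
    assoc_row("rs4", "A", "T", 0.10, eaf = NA)     # missing eaf -> drop
  )
  outcome <- gwas_table(dplyr::bind_rows(
    assoc_row("rs1", "A", "T", 0.20, eaf = 0.32),
    assoc_row("rs2", "A", "T", 0.20, eaf = 0.45),
    assoc_row("rs3", "C", "G", 0.20, eaf = 0.70),
    assoc_row("rs4", "A", "T", 0.20, eaf = 0.30)
  ), "out", "binary")
  h <- harmonize(exposure, outcome)
  aud <- audit_log(h)
  expect_equal(h$rsid, c("rs1", "rs3"))
  expect_equal(h$beta_outcome[h$rsid == "rs1"], 0.20)       # same side of 0.5
  expect_equal(h$beta_outcome[h$rsid == "rs3"], -0.20)      # opposite sides
  expect_equal(aud$action[aud$rsid == "rs2"], "dropped_palindrome")
  expect_equal(aud$action[aud$rsid == "rs4"], "dropped_palindrome")
  expect_equal(aud$detail[aud$rsid == "rs4"], "missing_eaf")

  # requiring the MAF condition in the exposure only is a config switch
  cfg <- mr_config(palindrome_maf_both = FALSE)
  exposure2 <- assoc_row("rs9", "A", "T", 0.1, eaf = 0.30)
  outcome2 <- gwas_table(assoc_row("rs9", "A", "T", 0.2, eaf = 0.45), "o", "binary")
  expect_equal(nrow(suppressWarnings(harmonize(exposure2, outcome2, cfg))), 1)
  expect_error(harmonize(exposure2, outcome2, mr_config()),
               class = "mrkit_harmonization_error")
})

test_that("proxies substitute the outcome record and the audit partitions the input", {
  exposure <- dplyr::bind_rows(
    assoc_row("rs1", "A", "G", 0.10, eaf = 0.3),
    assoc_row("rs2", "A", "G", 0.10, eaf = 0.3),   # missing, has proxy
    assoc_row("rs3", "A", "G", 0.10, eaf = 0.3),   # missing, no proxy
    assoc_row("rs4", "A", "C", 0.10, eaf = 0.3)    # allele mismatch in outcome
  )
  outcome <- gwas_table(dplyr::bind_rows(
    assoc_row("rs1", "A", "G", 0.20, eaf = 0.3),
    assoc_row("rs20", "A", "G", 0.15, eaf = 0.3),
    assoc_row("rs4", "A", "T", 0.10, eaf = 0.3)
  ), "out", "binary")
  ld <- ld_table(tibble::tibble(rsid_a = "rs2", rsid_b = "rs20", r2 = 0.9))
  proxies <- substitute_proxies(c("rs2", "rs3"), outcome, ld, 0.8)
  h <- harmonize(exposure, outcome, proxies = proxies)
  aud <- audit_log(h)
  expect_equal(aud$action[aud$rsid == "rs2"], "proxy_substituted")
  expect_equal(h$beta_outcome[h$rsid == "rs2"], 0.15)
  expect_equal(h$proxy[h$rsid == "rs2"], "rs20")
  expect_equal(aud$action[aud$rsid == "rs3"], "dropped_missing")
  expect_equal(aud$detail[aud$rsid == "rs4"], "allele_mismatch")
  # audit partition: every input instrument accounted for exactly once
  expect_equal(nrow(aud), nrow(exposure))
  expect_setequal(aud$rsid, exposure$rsid)
  expect_equal(sum(aud$action %in% c("kept", "allele_flipped", "proxy_substituted")),
               nrow(h))
})

test_that("harmonization is invariant to wholesale outcome-table re-orientation", {
  for (seed in c(3, 17, 92)) {
    sim <- simulate_mr(mr_scenario(J = 40, beta_true = 0.1, target_mean_f = 60,
                                   frac_palindromic = 0.3, frac_strand_flipped = 0.2,
                                   seed = seed))
    flipped <- sim$outcome
    tmp <- flipped$effect_allele
    flipped$effect_allele <- flipped$other_allele
    flipped$other_allele <- tmp
    flipped$beta <- -flipped$beta
    flipped$eaf <- 1 - flipped$eaf
    h1 <- harmonize(sim$exposure, sim$outcome)
    h2 <- harmonize(sim$exposure, flipped)
    expect_equal(h1$rsid, h2$rsid)
    expect_equal(h1$beta_outcome, h2$beta_outcome, tolerance = 1e-12)
    expect_equal(h1$eaf_outcome, h2$eaf_outcome, tolerance = 1e-12)
  }
})

test_that("the generator's flips and swaps are undone up to palindrome drops", {
  sim <- simulate_mr(mr_scenario(J = 60, beta_true = 0.3, se_y = 1e-3,
                                 gamma_range = c(0.05, 0.15), target_mean_f = 2000,
                                 frac_palindromic = 0.2, frac_strand_flipped = 0.3,
                                 seed = 5))
  h <- harmonize(sim$exposure, sim$outcome)
  # with near-noiseless outcome, every recovered ratio must sit near the
  # true effect; a wrong sign recovery would flip it to about -0.3
  ratios <- h$beta_outcome / h$beta_exposure
  expect_true(all(abs(ratios - 0.3) < 0.15))
  aud <- audit_log(h)
  expect_true(all(aud$action[!aud$rsid %in% h$rsid] == "dropped_palindrome"))
})
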