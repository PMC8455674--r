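# Synthetic two-sample GWAS summary statistics with known causal truth.
#
# The generator draws J independent instruments with positive true exposure
# effects gamma_j (effect alleles oriented to the exposure-increasing
# allele), sets the true outcome effect Gamma_j = beta_true * gamma_j +
# alpha_j with the pleiotropy alpha_j per regime, and observes both with
# independent normal noise (two-sample independence). Allele labels,
# frequencies, palindromes, strand flips, outcome omissions and in-LD
# proxies exercise the harmonization and proxy machinery.

#' Define a simulation scenario
#'
#' @param J Number of instruments.
#' @param beta_true True causal effect (log odds-ratio scale for binary
#'   outcomes; identity scale for continuous).
#' @param gamma_range Range of true per-variant exposure effects (uniform
#'   magnitudes; default `c(0.01, 0.15)`, typical of log-OR GWAS hits).
#' @param se_x,se_y Standard-error scales of the exposure and outcome
#'   association estimates (default 0.01 and 0.02; per-variant SEs are
#'   jittered around `se_x`).
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean pleiotropy),
#'   `"directional"` (mean `pleiotropy_mean`, independent of instrument
#'   strength, so InSIDE holds) or `"inside_violating"` (pleiotropy
#'   correlated with the true exposure effect).
#' @param center_pleiotropy In balanced mode, force the sample mean of the
#'   pleiotropic effects to exactly 0 (default `FALSE`: balanced means zero
#'   mean in expectation, as in a random draw of pleiotropic variants;
#'   exact centring induces negative cross-variant correlation).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-variant
#'   pleiotropic effects alpha_j.
#' @param outlier_indices,outlier_alpha Indices of planted outliers and the
#'   pleiotropic effect assigned to them (recycled).
#' @param maf_range Range of effect-allele frequencies (default
#'   `c(0.05, 0.95)`, so palindromes occur on both sides of the 0.42
#'   minor-allele-frequency rule).
#' @param frac_palindromic Fraction of variants given A/T or C/G alleles.
#' @param frac_strand_flipped Fraction of variants whose outcome-table
#'   alleles are reported on the opposite strand.
#' @param frac_effect_swapped Fraction of outcome records reporting the
#'   other allele as the effect allele (labels swapped, beta negated,
#'   frequency complemented), as happens when GWAS use different
#'   effect-allele conventions.
#' @param frac_missing Fraction of instruments omitted from the outcome
#'   table, each given one in-LD proxy (r2 drawn from \[0.8, 1\]).
#' @param target_mean_f Optional calibration: rescale `se_x` so the
#'   expected mean per-variant F-statistic equals this value (uses
#'   `E[(gamma_hat/se)^2] = (gamma/se)^2 + 1`).
#' @param outcome_type `"binary"` or `"continuous"` outcome trait.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   scenario.
#' @return An `mr_scenario` list.
#' @export
mr_scenario <- function(J = 110, beta_true = 0, gamma_range = c(0.01, 0.15),
                        se_x = 0.01, se_y = 0.02,
                        pleiotropy_mode = c("none", "balanced", "directional",
                                            "inside_violating"),
                        pleiotropy_mean = 0, pleiotropy_sd = 0,
                        center_pleiotropy = FALSE,
                        outlier_indices = integer(0), outlier_alpha = 0,
                        maf_range = c(0.05, 0.95),
                        frac_palindromic = 0.2, frac_strand_flipped = 0.1,
                        frac_effect_swapped = 0.3,
                        frac_missing = 0, target_mean_f = NULL,
                        outcome_type = c("binary", "continuous"), seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  if (J < 1) mr_abort("J must be >= 1", "mrkit_config_error")
  fracs <- c(frac_palindromic, frac_strand_flipped, frac_effect_swapped, frac_missing)
  if (any(fracs < 0 | fracs > 1)) mr_abort("fractions must lie in [0, 1]", "mrkit_config_error")
  if (se_x <= 0 || se_y <= 0) mr_abort("se scales must be positive", "mrkit_config_error")
  if (!is.null(target_mean_f) && target_mean_f <= 1) {
    mr_abort("target_mean_f must exceed 1", "mrkit_config_error")
  }
  if (frac_missing >= 1) {
    mr_abort("frac_missing must leave at least one instrument in the outcome",
             "mrkit_config_error")
  }
  if (length(outlier_indices) > 0 && max(outlier_indices) > J) {
    mr_abort("outlier_indices exceed J", "mrkit_config_error")
  }
  structure(as.list(environment()), class = "mr_scenario")
}

# draw the numeric core (true effects, pleiotropy, observed estimates)
draw_core <- function(sc) {
  J <- sc$J
  gamma <- stats::runif(J, sc$gamma_range[1], sc$gamma_range[2])
  if (!is.null(sc$target_mean_f)) {
    # Instruments in a selected set are all genome-wide significant, so the
    # per-variant noncentrality lambda_j = (gamma_j/se_xj)^2 is bounded well
    # away from 0; draw lambda_j uniform with mean target - 1, using
    # E[(gamma_hat/se)^2] = lambda_j + 1, and derive se_x from it.
    lmin <- min(34, sc$target_mean_f - 1)
    lmax <- 2 * (sc$target_mean_f - 1) - lmin
    lambda <- stats::runif(J, lmin, lmax)
    se_x <- gamma / sqrt(lambda)
  } else {
    se_x <- sc$se_x * stats::runif(J, 0.8, 1.2)
  }
  se_y <- rep_len(sc$se_y, J)
  alpha <- switch(sc$pleiotropy_mode,
    none = rep(0, J),
    balanced = {
      a <- stats::rnorm(J, 0, sc$pleiotropy_sd)
      if (isTRUE(sc$center_pleiotropy)) a - mean(a) else a
    },
    directional = stats::rnorm(J, sc$pleiotropy_mean, sc$pleiotropy_sd),
    inside_violating = {
      z <- (gamma - mean(gamma)) / stats::sd(gamma)
      rho <- 0.7
      sc$pleiotropy_mean +
        sc$pleiotropy_sd * (rho * z + sqrt(1 - rho^2) * stats::rnorm(J))
    }
  )
  if (length(sc$outlier_indices) > 0) {
    alpha[sc$outlier_indices] <- rep_len(sc$outlier_alpha, length(sc$outlier_indices))
  }
  Gamma <- sc$beta_true * gamma + alpha
  tibble::tibble(
    rsid = sprintf("rs%d", seq_len(J)),
    gamma = gamma, alpha = alpha, Gamma = Gamma,
    beta_exposure = stats::rnorm(J, gamma, se_x),
    se_exposure = se_x,
    beta_outcome = stats::rnorm(J, Gamma, se_y),
    se_outcome = se_y
  )
}

#' Simulate a ready-harmonized instrument set
#'
#' Fast path for estimator validation: draws the numeric core of a
#' scenario (true effects, pleiotropy, noisy observations) and returns it
#' directly as an `mr_harmonized` set, skipping the allele bookkeeping.
#'
#' @param scenario An [mr_scenario()].
#' @return List with `set` (an `mr_harmonized`) and `truth` (tibble of
#'   true per-variant effects plus `beta_true` and outlier indices as
#'   attributes).
#' @export
simulate_harmonized <- function(scenario) {
  core <- withr::with_seed(as.integer(scenario$seed), draw_core(scenario))
  df <- core[, c("rsid", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome")]
  df$proxy <- NA_character_
  df$eaf_exposure <- NA_real_
  df$eaf_outcome <- NA_real_
  df$action <- "kept"
  set <- new_harmonized(
    df[, c("rsid", "proxy", "beta_exposure", "se_exposure", "eaf_exposure",
           "beta_outcome", "se_outcome", "eaf_outcome", "action")],
    audit = tibble::tibble(rsid = df$rsid, proxy = NA_character_,
                           action = "kept", detail = NA_character_))
  truth <- core[, c("rsid", "gamma", "alpha", "Gamma")]
  attr(truth, "beta_true") <- scenario$beta_true
  attr(truth, "outlier_indices") <- scenario$outlier_indices
  list(set = set, truth = truth)
}

pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
nonpal_pairs <- list(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                     c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))

#' Simulate a full two-sample dataset
#'
#' Generates exposure and outcome summary-statistic tables, an LD table
#' and the ground truth for one scenario. Instruments get allele labels
#' and frequencies (a configurable fraction palindromic), a fraction of
#' outcome records are reported on the opposite strand, and a fraction of
#' instruments are omitted from the outcome table and replaced by an
#' in-LD proxy variant (r2 drawn from \[0.8, 1\]); proxies carry the same
#' allele pair and frequency as the variant they tag. Exposure and
#' outcome noise are drawn independently (two-sample design). Genome-wide
#' significance of the instruments follows from the scenario's
#' instrument-strength settings rather than from any post-selection.
#'
#' @param scenario An [mr_scenario()].
#' @return List with `exposure` and `outcome` (`gwas_tbl`), `ld`
#'   (`ld_tbl`), and `truth` (list with `beta_true`, per-variant `gamma`
#'   and `alpha`, outlier indices, palindrome / strand-flip / proxy
#'   bookkeeping).
#' @export
simulate_mr <- function(scenario) {
  sc <- scenario
  withr::with_seed(as.integer(sc$seed), {
    core <- draw_core(sc)
    J <- sc$J
    n_pal <- round(sc$frac_palindromic * J)
    is_pal <- seq_len(J) %in% sample.int(J, n_pal)
    pick <- function(pal) {
      pairs <- if (pal) pal_pairs else nonpal_pairs
      unlist(pairs[sample.int(length(pairs), 1)])
    }
    alleles <- t(vapply(is_pal, pick, character(2)))
    eaf_true <- stats::runif(J, sc$maf_range[1], sc$maf_range[2])
    eaf_x <- pmin(0.999, pmax(0.001, eaf_true + stats::rnorm(J, 0, 0.005)))
    eaf_y <- pmin(0.999, pmax(0.001, eaf_true + stats::rnorm(J, 0, 0.005)))

    exposure <- tibble::tibble(
      rsid = core$rsid,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf_x,
      beta = core$beta_exposure, se = core$se_exposure,
      pvalue = pmax(.Machine$double.xmin,
        2 * stats::pnorm(-abs(core$beta_exposure / core$se_exposure)))
    )

    # outcome table: same biological orientation; strand flips relabel a
    # fraction of records on the complementary strand (no sign change)
    flipped <- seq_len(J) %in% sample.int(J, round(sc$frac_strand_flipped * J))
    ea_y <- ifelse(flipped, strand_complement(alleles[, 1]), alleles[, 1])
    oa_y <- ifelse(flipped, strand_complement(alleles[, 2]), alleles[, 2])
    # effect-allele convention differences: report the other allele as the
    # effect allele for a fraction of records
    swapped <- seq_len(J) %in% sample.int(J, round(sc$frac_effect_swapped * J))
    beta_y <- ifelse(swapped, -core$beta_outcome, core$beta_outcome)
    eaf_y <- ifelse(swapped, 1 - eaf_y, eaf_y)
    tmp <- ea_y
    ea_y <- ifelse(swapped, oa_y, ea_y)
    oa_y <- ifelse(swapped, tmp, oa_y)
    outcome <- tibble::tibble(
      rsid = core$rsid,
      effect_allele = ea_y, other_allele = oa_y,
      eaf = eaf_y,
      beta = beta_y, se = core$se_outcome,
      pvalue = pmax(.Machine$double.xmin,
        2 * stats::pnorm(-abs(beta_y / core$se_outcome)))
    )

    # omit a fraction from the outcome; add one in-LD proxy per omission
    n_miss <- floor(sc$frac_missing * J)
    miss_idx <- if (n_miss > 0) sample.int(J, n_miss) else integer(0)
    ld_rows <- tibble::tibble(rsid_a = character(0), rsid_b = character(0),
                              r2 = numeric(0))
    if (n_miss > 0) {
      proxy_rsid <- sprintf("rs%d", 1000000L + miss_idx)
      r2 <- stats::runif(n_miss, 0.8, 1)
      proxy_rows <- outcome[miss_idx, ]
      proxy_rows$rsid <- proxy_rsid
      # the proxy tags the same signal; respect the record's allele coding
      proxy_sign <- ifelse(swapped[miss_idx], -1, 1)
      proxy_rows$beta <- proxy_sign *
        stats::rnorm(n_miss, core$Gamma[miss_idx], core$se_outcome[miss_idx])
      proxy_rows$pvalue <- pmax(.Machine$double.xmin,
        2 * stats::pnorm(-abs(proxy_rows$beta / proxy_rows$se)))
      outcome <- dplyr::bind_rows(outcome[-miss_idx, ], proxy_rows)
      ld_rows <- tibble::tibble(rsid_a = core$rsid[miss_idx], rsid_b = proxy_rsid, r2 = r2)
    }

    truth <- list(
      beta_true = sc$beta_true,
      rsid = core$rsid, gamma = core$gamma, alpha = core$alpha,
      outlier_indices = sc$outlier_indices,
      palindromic = core$rsid[is_pal],
      strand_flipped = core$rsid[flipped],
      effect_swapped = core$rsid[swapped],
      missing_from_outcome = core$rsid[miss_idx],
      proxy_map = if (n_miss > 0) {
        stats::setNames(sprintf("rs%d", 1000000L + miss_idx), core$rsid[miss_idx])
      } else character(0)
    )

    list(
      exposure = gwas_table(exposure, trait_name = "exposure",
                            trait_type = "binary", provenance = "simulated"),
      outcome = gwas_table(outcome, trait_name = "outcome",
                           trait_type = sc$outcome_type, provenance = "simulated"),
      ld = ld_table(ld_rows),
      truth = truth
    )
  })
}

#' Catalogue of ready-made simulation scenarios
#'
#' Named presets covering the qualitative regimes the estimators face:
#'
#' * `valid_110` — the study-like instrument set: J = 110 instruments
#'   calibrated to a mean F-statistic of 89.3, no pleiotropy, null effect.
#' * `valid_recovery` — J = 100 strong instruments (mean F ~ 900, so
#'   measurement-error dilution is negligible), true log-OR 0.2, no
#'   pleiotropy: parameter-recovery regime.
#' * `null_balanced` — true effect 0 with balanced pleiotropy (mean 0):
#'   type-I-error regime for the random-effects IVW.
#' * `directional_inside` — directional pleiotropy (mean 0.05) independent
#'   of instrument strength: MR-Egger's intercept should recover 0.05 and
#'   its slope should out-perform IVW.
#' * `inside_violating` — pleiotropy correlated with instrument strength:
#'   even MR-Egger is biased; used as a contrast.
#' * `presso_outliers` — 5 planted outliers (pleiotropy 10 x se_y) among
#'   50 instruments: MR-PRESSO detection regime.
#' * `proxy_palindrome_mix` — 10% of instruments missing from the outcome
#'   with in-LD proxies, 30% palindromic, 15% strand-flipped: harmonization
#'   plumbing regime.
#'
#' @param seed Base seed stored in every preset.
#' @return Named list of [mr_scenario()] objects.
#' @export
scenario_presets <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    valid_110 = mr_scenario(J = 110, beta_true = 0, target_mean_f = 89.3,
                            frac_palindromic = 0.2, frac_strand_flipped = 0.1,
                            seed = seed),
    valid_recovery = mr_scenario(J = 100, beta_true = 0.2, se_x = 0.003,
                                 frac_palindromic = 0, frac_strand_flipped = 0,
                                 seed = seed),
    null_balanced = mr_scenario(J = 100, beta_true = 0, se_x = 0.003,
                                pleiotropy_mode = "balanced", pleiotropy_sd = 0.02,
                                frac_palindromic = 0, frac_strand_flipped = 0,
                                seed = seed),
    directional_inside = mr_scenario(J = 100, beta_true = 0.2, se_x = 0.003,
                                     pleiotropy_mode = "directional",
                                     pleiotropy_mean = 0.05, pleiotropy_sd = 0.02,
                                     frac_palindromic = 0, frac_strand_flipped = 0,
                                     seed = seed),
    inside_violating = mr_scenario(J = 100, beta_true = 0.2, se_x = 0.003,
                                   pleiotropy_mode = "inside_violating",
                                   pleiotropy_mean = 0.05, pleiotropy_sd = 0.05,
                                   frac_palindromic = 0, frac_strand_flipped = 0,
                                   seed = seed),
    presso_outliers = mr_scenario(J = 50, beta_true = 0.2, se_x = 0.003,
                                  outlier_indices = 1:5, outlier_alpha = 0.2,
                                  frac_palindromic = 0, frac_strand_flipped = 0,
                                  seed = seed),
    proxy_palindrome_mix = mr_scenario(J = 110, beta_true = 0.1,
                                       target_mean_f = 89.3,
                                       frac_palindromic = 0.3,
                                       frac_strand_flipped = 0.15,
                                       frac_missing = 0.1, seed = seed)
  )
}

#' Simulate a pair of traits for bi-directional analysis
#'
#' Builds two traits, each with its own instrument set, where each trait's
#' table also carries the outcome-side associations of the other trait's
#' instruments, so [run_bidirectional()] can run both directions. A chosen
#' number of instruments are shared between the two sets (instrument-grade
#' in both traits) to exercise the overlap sensitivity re-run.
#'
#' @param scenario_ab Scenario for the A-to-B direction (trait A
#'   instruments; `beta_true` is the A-on-B effect).
#' @param scenario_ba Scenario for the B-to-A direction.
#' @param n_shared Number of instruments shared between the two sets.
#' @param seed Integer seed.
#' @return List with `trait_a`, `trait_b` (`gwas_tbl`), `ld` and `truth`.
#' @export
simulate_mr_pair <- function(scenario_ab, scenario_ba, n_shared = 0, seed = 1L) {
  sc_ab <- scenario_ab; sc_ab$seed <- as.integer(seed)
  sc_ba <- scenario_ba; sc_ba$seed <- as.integer(seed) + 1L
  sim_ab <- simulate_mr(sc_ab)
  sim_ba <- simulate_mr(sc_ba)
  # re-key B's instruments so the two sets are disjoint, then share some
  offset <- 500000L
  rekey <- function(tbl, old, new) {
    m <- match(tbl$rsid, old)
    hit <- !is.na(m)
    tbl$rsid[hit] <- new[m[hit]]
    tbl
  }
  old_b <- sim_ba$exposure$rsid
  new_b <- sprintf("rs%d", offset + seq_along(old_b))
  if (n_shared > 0) {
    n_shared <- min(n_shared, length(old_b), nrow(sim_ab$exposure))
    new_b[seq_len(n_shared)] <- sim_ab$exposure$rsid[seq_len(n_shared)]
  }
  exp_b <- rekey(sim_ba$exposure, old_b, new_b)
  out_a <- rekey(sim_ba$outcome, old_b, new_b)
  shared <- if (n_shared > 0) new_b[seq_len(n_shared)] else character(0)
  # shared variants must carry one consistent allele coding across tables
  if (length(shared) > 0) {
    src <- sim_ab$exposure[match(shared, sim_ab$exposure$rsid), ]
    for (col in c("effect_allele", "other_allele", "eaf")) {
      i <- match(shared, exp_b$rsid)
      exp_b[[col]][i[!is.na(i)]] <- src[[col]][!is.na(i)]
      j <- match(shared, out_a$rsid)
      out_a[[col]][j[!is.na(j)]] <- src[[col]][!is.na(j)]
    }
  }

  combine <- function(own, cross, nm, type) {
    cross <- cross[!(cross$rsid %in% own$rsid), , drop = FALSE]
    gwas_table(dplyr::bind_rows(own, cross), trait_name = nm, trait_type = type,
               provenance = "simulated")
  }
  trait_a <- combine(sim_ab$exposure, out_a, "trait_a", "binary")
  trait_b <- combine(exp_b, sim_ab$outcome, "trait_b", "binary")
  ld_ba <- sim_ba$ld
  for (col in c("rsid_a", "rsid_b")) {
    m <- match(ld_ba[[col]], old_b)
    ld_ba[[col]][!is.na(m)] <- new_b[m[!is.na(m)]]
  }
  ld <- ld_table(dplyr::bind_rows(sim_ab$ld, ld_ba))
  list(trait_a = trait_a, trait_b = trait_b, ld = ld,
       truth = list(a_to_b = sim_ab$truth, b_to_a = sim_ba$truth,
                    shared = shared))
}

#' Write a simulated dataset to delimited text plus a truth JSON
#'
#' Emits `exposure.tsv`, `outcome.tsv`, `ld.tsv` and `truth.json` into a
#' directory, in the formats [read_gwas()] and [read_ld()] read back.
#'
#' @param sim Result of [simulate_mr()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulated <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(tibble::as_tibble(sim$exposure), file.path(dir, "exposure.tsv"))
  readr::write_tsv(tibble::as_tibble(sim$outcome), file.path(dir, "outcome.tsv"))
  readr::write_tsv(tibble::as_tibble(sim$ld), file.path(dir, "ld.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
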