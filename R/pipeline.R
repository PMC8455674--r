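# Study orchestration: one exposure->outcome direction, bi-directional
# batteries with overlap sensitivity re-runs, confounder screen,
# Bonferroni control.

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha_family Family-wise significance level.
#' @param n_tests Number of tests in the family (e.g. 16 for eight traits
#'   tested in two directions).
#' @return `alpha_family / n_tests`.
#' @export
bonferroni_threshold <- function(alpha_family, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    mr_abort("n_tests must be >= 1", "mrkit_config_error")
  }
  alpha_family / n_tests
}

#' Classify a p-value against nominal and Bonferroni thresholds
#'
#' @param p IVW p-value(s).
#' @param alpha Nominal level (default 0.05).
#' @param bonferroni Bonferroni-corrected level (default `alpha`).
#' @return Character vector in `"bonferroni"`, `"nominal"`, `"null"`.
#' @export
significance_tier <- function(p, alpha = 0.05, bonferroni = alpha) {
  dplyr::case_when(
    p < bonferroni ~ "bonferroni",
    p < alpha ~ "nominal",
    TRUE ~ "null"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("[", stage, "] ", conditionMessage(e)),
                 class = c("mrkit_stage_error", class(e)[1]), parent = e)
  })
}

#' Run one exposure-to-outcome MR direction end to end
#'
#' Variant filtering, instrument selection, greedy clumping, proxy
#' substitution, allele harmonization, instrument-strength computation,
#' the estimator battery and MR-PRESSO, with a per-stage audit trail.
#' Errors are labelled with the stage that raised them.
#'
#' @param exposure,outcome `gwas_tbl` tables for the two traits.
#' @param ld An `ld_tbl` (or `NULL`).
#' @param config An [mr_config()].
#' @param seed Integer seed driving all stochastic stages.
#' @param n_tests Family size for the Bonferroni tier (default 16: eight
#'   traits in two directions).
#' @return An `mr_direction` object; [tidy()] gives the per-method results
#'   table, [glance()] the one-row direction summary.
#' @export
run_direction <- function(exposure, outcome, ld = NULL, config = mr_config(),
                          seed = 1L, n_tests = 16) {
  exposure <- with_stage("filter", filter_variants(exposure))
  outcome_f <- with_stage("filter", filter_variants(outcome))
  candidates <- with_stage("select", select_instruments(exposure, config))
  kept_rsids <- with_stage("clump", greedy_clump(candidates, ld, config$clump_r2))
  instruments <- candidates[match(kept_rsids, candidates$rsid), , drop = FALSE]
  missing <- setdiff(instruments$rsid, outcome_f$rsid)
  proxies <- with_stage("proxy",
    substitute_proxies(missing, outcome_f, ld, config$proxy_r2))
  hset <- with_stage("harmonize",
    harmonize(instruments, outcome_f, config, proxies = proxies))
  fstat <- with_stage("strength", mean_f_statistic(hset))
  battery <- with_stage("estimate",
    mr_estimate_all(hset, trait_type = trait_type_of(outcome, "binary"),
                    config = config, seed = as.integer(seed)))
  ivw_p <- battery$estimates$ivw$p_value
  structure(list(
    exposure = trait_name_of(exposure, "exposure"),
    outcome = trait_name_of(outcome, "outcome"),
    trait_type = trait_type_of(outcome, "binary"),
    instruments = hset$rsid,
    n_snp = nrow(hset),
    f_statistic = fstat$mean_f,
    f_per_snp = fstat$per_snp,
    harmonized = hset,
    battery = battery,
    presso = battery$presso,
    audit = audit_log(hset),
    significance_tier = significance_tier(
      ivw_p, config$alpha, bonferroni_threshold(config$alpha, n_tests)),
    config = config, seed = as.integer(seed), sensitivity = NULL
  ), class = "mr_direction")
}

#' Run both directions between two traits, with overlap sensitivity
#'
#' Runs trait A as exposure for trait B and vice versa, flags instruments
#' of each direction that are identical to or in high LD (r2 at or above
#' `config$overlap_r2`) with the reverse direction's instruments, and when
#' any are flagged re-runs that direction without them, attaching the
#' re-run as `sensitivity`.
#'
#' @param trait_a,trait_b `gwas_tbl` tables, each instrument-grade for its
#'   own trait.
#' @param ld An `ld_tbl` (or `NULL`).
#' @param config An [mr_config()].
#' @param seed Integer seed.
#' @param n_tests Bonferroni family size.
#' @return List of two `mr_direction` objects (`a_to_b`, `b_to_a`), each
#'   possibly carrying a `sensitivity` re-run and `overlap_rsids`.
#' @export
run_bidirectional <- function(trait_a, trait_b, ld = NULL, config = mr_config(),
                              seed = 1L, n_tests = 16) {
  ab <- run_direction(trait_a, trait_b, ld, config, seed = seed, n_tests = n_tests)
  ba <- run_direction(trait_b, trait_a, ld, config, seed = seed + 1L, n_tests = n_tests)
  add_sensitivity <- function(dir, other, tbl_exp, tbl_out, seed_off) {
    overlap <- flag_overlap(dir$instruments, other$instruments, ld, config$overlap_r2)
    dir$overlap_rsids <- overlap
    if (length(overlap) > 0 && length(setdiff(dir$instruments, overlap)) >= 1) {
      exp2 <- tbl_exp[!(tbl_exp$rsid %in% overlap), , drop = FALSE]
      attributes(exp2)[c("trait_name", "trait_type", "provenance")] <-
        attributes(tbl_exp)[c("trait_name", "trait_type", "provenance")]
      class(exp2) <- class(tbl_exp)
      sens <- run_direction(exp2, tbl_out, ld, config, seed = seed + seed_off,
                            n_tests = n_tests)
      sens$audit <- dplyr::bind_rows(
        sens$audit,
        tibble::tibble(rsid = overlap, proxy = NA_character_,
                       action = "dropped_overlap", detail = "overlap_with_reverse")
      )
      dir$sensitivity <- sens
    }
    dir
  }
  ab <- add_sensitivity(ab, ba, trait_a, trait_b, 2L)
  ba <- add_sensitivity(ba, ab, trait_b, trait_a, 3L)
  list(a_to_b = ab, b_to_a = ba)
}

#' Screen instruments against candidate confounders
#'
#' Runs the genetic predictors of the exposure against each confounder
#' trait with the same estimator battery, reporting mean differences for
#' continuous confounders and odds ratios for binary ones — the layout used
#' to check the independence assumption (education, deprivation, smoking,
#' alcohol, physical activity analogues).
#'
#' @param exposure The exposure `gwas_tbl`.
#' @param confounders Named list of confounder `gwas_tbl` tables.
#' @param ld An `ld_tbl` (or `NULL`).
#' @param config An [mr_config()].
#' @param seed Integer seed (each confounder gets a derived seed).
#' @return An `mr_screen` object (list of `mr_direction`); [tidy()] binds
#'   the per-confounder tables.
#' @export
confounder_screen <- function(exposure, confounders, ld = NULL,
                              config = mr_config(), seed = 1L) {
  if (length(confounders) == 0) mr_abort("no confounder tables supplied", "mrkit_input_error")
  res <- purrr::imap(confounders, function(tbl, nm) {
    run_direction(exposure, tbl, ld, config,
                  seed = seed + match(nm, names(confounders)),
                  n_tests = length(confounders))
  })
  structure(res, class = "mr_screen")
}
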