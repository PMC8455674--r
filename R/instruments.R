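# Instrument selection: significance threshold, greedy LD clumping,
# proxy substitution, cross-direction overlap, instrument strength.

#' Instrument-selection and analysis configuration
#'
#' @param p_threshold Genome-wide significance cutoff for instruments
#'   (default 5e-8; relax to 5e-6 for outcomes with few significant hits).
#' @param clump_r2 LD-independence threshold for greedy clumping
#'   (instruments kept pairwise r2 below this; default 0.001).
#' @param proxy_r2 Minimum r2 for a proxy variant substituting an
#'   instrument missing from the outcome GWAS (default 0.8).
#' @param palindrome_maf_max Maximum minor-allele frequency at which a
#'   palindromic (A/T or C/G) variant can still be aligned by allele
#'   frequency (default 0.42); above it the variant is dropped.
#' @param palindrome_maf_both Require the MAF condition in both the
#'   exposure and the outcome sample (default `TRUE`, conservative) or in
#'   the exposure only.
#' @param overlap_r2 r2 at or above which an instrument is considered
#'   overlapping with a reverse-direction instrument (default 0.8).
#' @param alpha Nominal two-sided significance level (default 0.05).
#' @param n_boot Bootstrap replicates for the weighted-median standard
#'   error (default 1000).
#' @param n_sim MR-PRESSO simulation count (default 1000).
#' @return An `mr_config` list.
#' @export
mr_config <- function(p_threshold = 5e-8, clump_r2 = 0.001, proxy_r2 = 0.8,
                      palindrome_maf_max = 0.42, palindrome_maf_both = TRUE,
                      overlap_r2 = 0.8, alpha = 0.05,
                      n_boot = 1000, n_sim = 1000) {
  thresholds <- c(p_threshold = p_threshold, clump_r2 = clump_r2,
                  proxy_r2 = proxy_r2, palindrome_maf_max = palindrome_maf_max,
                  overlap_r2 = overlap_r2, alpha = alpha)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    mr_abort("all thresholds must lie in (0, 1)", "mrkit_config_error")
  }
  if (proxy_r2 <= clump_r2) {
    mr_abort("proxy_r2 must exceed clump_r2", "mrkit_config_error")
  }
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 proxy_r2 = proxy_r2, palindrome_maf_max = palindrome_maf_max,
                 palindrome_maf_both = palindrome_maf_both,
                 overlap_r2 = overlap_r2, alpha = alpha,
                 n_boot = as.integer(n_boot), n_sim = as.integer(n_sim)),
            class = "mr_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected so typos surface as configuration errors.
#'
#' @param path YAML file whose keys match the arguments of [mr_config()].
#' @return An `mr_config`.
#' @export
read_mr_config <- function(path) {
  if (!file.exists(path)) mr_abort(paste0("file not found: ", path), "mrkit_input_error")
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(mr_config)))
  if (length(unknown) > 0) {
    mr_abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")),
             "mrkit_config_error")
  }
  do.call(mr_config, vals)
}

#' Select candidate instruments by significance
#'
#' Returns the variants whose association p-value falls below the
#' instrument threshold, sorted by ascending p-value — the input order the
#' greedy clumping step assumes.
#'
#' @param tbl A `gwas_tbl` that has passed [filter_variants()].
#' @param config An [mr_config()].
#' @return The candidate rows as a tibble sorted by `pvalue`.
#' @export
select_instruments <- function(tbl, config = mr_config()) {
  hits <- tbl[tbl$pvalue < config$p_threshold, , drop = FALSE]
  if (nrow(hits) == 0) {
    mr_abort(paste0("no variants reach the instrument p-value threshold ",
                    format(config$p_threshold)), "mrkit_selection_error")
  }
  hits[order(hits$pvalue, hits$rsid), , drop = FALSE]
}

#' Greedy LD clumping
#'
#' Iterates candidates in the supplied order (ascending p-value) and keeps a
#' variant only if its r2 with every already-kept variant is below
#' `clump_r2`. Deterministic given the input order.
#'
#' @param candidates Character vector of rsIDs sorted by ascending p-value,
#'   or a data frame with an `rsid` column in that order.
#' @param ld An `ld_tbl` (or `NULL` for no LD).
#' @param clump_r2 Independence threshold (default 0.001).
#' @return Character vector of retained rsIDs, in input order.
#' @export
greedy_clump <- function(candidates, ld = NULL, clump_r2 = 0.001) {
  if (is.data.frame(candidates)) candidates <- candidates$rsid
  kept <- character(0)
  for (rs in candidates) {
    if (length(kept) == 0 || all(ld_r2(ld, rs, kept) < clump_r2)) {
      kept <- c(kept, rs)
    }
  }
  kept
}

#' Find proxy variants for instruments missing from the outcome GWAS
#'
#' For each missing instrument, selects the outcome-present variant with the
#' highest r2 at or above `proxy_r2`; ties are broken by smaller outcome
#' p-value, then lexicographic rsID. Instruments without a qualifying proxy
#' get `NA` (and are dropped downstream).
#'
#' @param missing Character vector of instrument rsIDs absent from the
#'   outcome table.
#' @param outcome The outcome `gwas_tbl`.
#' @param ld An `ld_tbl`.
#' @param proxy_r2 Minimum acceptable r2 (default 0.8).
#' @return Tibble with columns `rsid`, `proxy` (NA if none), `r2`.
#' @export
substitute_proxies <- function(missing, outcome, ld, proxy_r2 = 0.8) {
  pick <- function(rs) {
    if (is.null(ld) || nrow(ld) == 0) return(c(NA_character_, NA_real_))
    cand <- ld[(ld$rsid_a == rs | ld$rsid_b == rs) & ld$r2 >= proxy_r2, , drop = FALSE]
    if (nrow(cand) == 0) return(c(NA_character_, NA_real_))
    other <- ifelse(cand$rsid_a == rs, cand$rsid_b, cand$rsid_a)
    present <- other %in% outcome$rsid
    if (!any(present)) return(c(NA_character_, NA_real_))
    other <- other[present]; r2 <- cand$r2[present]
    p_out <- outcome$pvalue[match(other, outcome$rsid)]
    ord <- order(-r2, p_out, other)
    c(other[ord[1]], r2[ord[1]])
  }
  res <- vapply(missing, pick, character(2))
  tibble::tibble(rsid = missing,
                 proxy = unname(res[1, ]),
                 r2 = suppressWarnings(as.numeric(res[2, ])))
}

#' Is an allele pair palindromic?
#'
#' Palindromic variants are coded A/T or C/G; their strand cannot be
#' resolved from allele labels alone.
#'
#' @param effect_allele,other_allele Single-base allele vectors.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele); b <- toupper(other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Flag instruments overlapping a reverse-direction instrument set
#'
#' An instrument overlaps when it is identical to, or in LD at or above
#' `r2` with, any instrument of the reverse direction. Flagged instruments
#' drive the sensitivity re-run of [run_bidirectional()].
#'
#' @param exposure_instruments,reverse_instruments Character vectors of rsIDs.
#' @param ld An `ld_tbl` (or `NULL`).
#' @param r2 Overlap threshold (default 0.8).
#' @return Character vector of flagged exposure instruments.
#' @export
flag_overlap <- function(exposure_instruments, reverse_instruments, ld = NULL, r2 = 0.8) {
  if (length(exposure_instruments) == 0 || length(reverse_instruments) == 0) {
    mr_abort("both instrument lists must be non-empty", "mrkit_input_error")
  }
  flagged <- vapply(exposure_instruments, function(rs) {
    rs %in% reverse_instruments || any(ld_r2(ld, rs, reverse_instruments) >= r2)
  }, logical(1))
  exposure_instruments[flagged]
}

#' Instrument strength: mean per-variant F-statistic
#'
#' The summary-data approximation F_j = (beta_exposure / se_exposure)^2 per
#' variant; the mean over instruments summarises strength, with values above
#' 10 conventionally indicating low weak-instrument bias.
#'
#' @param dat A harmonized instrument set (or any data frame with
#'   `beta_exposure` and `se_exposure` columns).
#' @return List with `mean_f` (scalar) and `per_snp` (tibble of `rsid`, `f`).
#' @export
mean_f_statistic <- function(dat) {
  if (nrow(dat) < 1) mr_abort("need at least one instrument", "mrkit_input_error")
  f <- (dat$beta_exposure / dat$se_exposure)^2
  list(mean_f = mean(f),
       per_snp = tibble::tibble(rsid = dat$rsid %||% as.character(seq_along(f)), f = f))
}
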