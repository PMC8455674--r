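# Allele harmonization of exposure instruments against an outcome GWAS.

strand_complement <- function(x) chartr("ACGT", "TGCA", toupper(x))

new_harmonized <- function(df, audit) {
  out <- tibble::as_tibble(df)
  attr(out, "audit") <- audit
  class(out) <- c("mr_harmonized", class(tibble::tibble()))
  out
}

#' Harmonize exposure instruments with outcome associations
#'
#' Aligns each instrument's outcome effect onto the exposure's effect
#' allele:
#' * matching alleles are kept as-is;
#' * swapped alleles (outcome effect allele equals the exposure other
#'   allele) negate the outcome beta and complement its frequency;
#' * alleles matching only after strand complement (A<->T, C<->G) are
#'   complemented first, then the same rules apply;
#' * palindromic variants (A/T or C/G) cannot be resolved from labels, so
#'   they are aligned by effect-allele frequency: after any label-based
#'   swap, the orientation is accepted when the exposure and outcome
#'   frequencies fall on the same side of 0.5 and reversed otherwise. This
#'   is only attempted when the minor-allele frequency is at most
#'   `palindrome_maf_max` (in both samples by default) and both
#'   frequencies are present; otherwise the variant is dropped.
#'
#' Instruments absent from the outcome table use the outcome record of
#' their proxy when one is supplied. Every input instrument is accounted
#' for exactly once in the audit with an action in `kept`,
#' `allele_flipped`, `proxy_substituted`, `dropped_palindrome`,
#' `dropped_missing`.
#'
#' @param exposure Instrument rows (a `gwas_tbl` subset) for the exposure.
#' @param outcome The outcome `gwas_tbl`.
#' @param config An [mr_config()].
#' @param proxies Optional tibble from [substitute_proxies()].
#' @return An `mr_harmonized` tibble with columns `rsid`, `proxy`,
#'   `beta_exposure`, `se_exposure`, `eaf_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`, `action`; the full audit (including
#'   dropped instruments) is in `attr(, "audit")`.
#' @export
harmonize <- function(exposure, outcome, config = mr_config(), proxies = NULL) {
  if (nrow(exposure) == 0) mr_abort("no exposure instruments", "mrkit_input_error")
  lookup <- exposure$rsid
  proxy_of <- rep(NA_character_, nrow(exposure))
  if (!is.null(proxies) && nrow(proxies) > 0) {
    m <- match(exposure$rsid, proxies$rsid)
    use <- !is.na(m) & !is.na(proxies$proxy[m]) & !(exposure$rsid %in% outcome$rsid)
    proxy_of[use] <- proxies$proxy[m[use]]
    lookup[use] <- proxy_of[use]
  }
  om <- match(lookup, outcome$rsid)

  n <- nrow(exposure)
  action <- rep(NA_character_, n)
  detail <- rep(NA_character_, n)
  beta_out <- eaf_out <- se_out <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    if (is.na(om[i])) {
      action[i] <- "dropped_missing"; detail[i] <- "absent_from_outcome"
      next
    }
    o <- outcome[om[i], ]
    ea_x <- exposure$effect_allele[i]; oa_x <- exposure$other_allele[i]
    ea_y <- o$effect_allele;           oa_y <- o$other_allele
    b_y <- o$beta; f_y <- o$eaf
    pal <- is_palindromic(ea_x, oa_x)

    if (!pal) {
      if (ea_y == ea_x && oa_y == oa_x) {
        # direct match
      } else if (ea_y == oa_x && oa_y == ea_x) {
        b_y <- -b_y; f_y <- 1 - f_y
      } else if (strand_complement(ea_y) == ea_x && strand_complement(oa_y) == oa_x) {
        detail[i] <- "strand_complement"
      } else if (strand_complement(ea_y) == oa_x && strand_complement(oa_y) == ea_x) {
        b_y <- -b_y; f_y <- 1 - f_y
        detail[i] <- "strand_complement"
      } else {
        action[i] <- "dropped_missing"; detail[i] <- "allele_mismatch"
        next
      }
    } else {
      # palindromic: outcome alleles must form the same base pair
      same_pair <- setequal(c(ea_y, oa_y), c(ea_x, oa_x))
      if (!same_pair) {
        action[i] <- "dropped_missing"; detail[i] <- "allele_mismatch"
        next
      }
      f_x <- exposure$eaf[i]
      if (is.na(f_x) || is.na(f_y)) {
        action[i] <- "dropped_palindrome"; detail[i] <- "missing_eaf"
        next
      }
      maf_ok <- min(f_x, 1 - f_x) <= config$palindrome_maf_max
      if (isTRUE(config$palindrome_maf_both)) {
        maf_ok <- maf_ok && min(f_y, 1 - f_y) <= config$palindrome_maf_max
      }
      if (!maf_ok) {
        action[i] <- "dropped_palindrome"; detail[i] <- "maf_above_threshold"
        next
      }
      if (ea_y == oa_x) {            # label-based swap first
        b_y <- -b_y; f_y <- 1 - f_y
      }
      same_side <- (f_x - 0.5) * (f_y - 0.5) > 0
      if (!same_side) {              # strand flip detected by frequency
        b_y <- -b_y; f_y <- 1 - f_y
        detail[i] <- paste(stats::na.omit(c(detail[i], "frequency_flip")), collapse = "+")
      }
    }
    sign_flipped <- !is.na(b_y) && !is.na(o$beta) && (sign(b_y) != sign(o$beta)) && o$beta != 0
    action[i] <- if (!is.na(proxy_of[i])) "proxy_substituted" else if (sign_flipped) "allele_flipped" else "kept"
    beta_out[i] <- b_y; eaf_out[i] <- f_y; se_out[i] <- o$se
  }

  audit <- tibble::tibble(rsid = exposure$rsid, proxy = proxy_of,
                          action = action, detail = detail)
  keep <- action %in% c("kept", "allele_flipped", "proxy_substituted")
  if (!any(keep)) {
    mr_abort("no instruments survived harmonization", "mrkit_harmonization_error")
  }
  df <- tibble::tibble(
    rsid = exposure$rsid[keep],
    proxy = proxy_of[keep],
    beta_exposure = exposure$beta[keep],
    se_exposure = exposure$se[keep],
    eaf_exposure = exposure$eaf[keep],
    beta_outcome = beta_out[keep],
    se_outcome = se_out[keep],
    eaf_outcome = eaf_out[keep],
    action = action[keep]
  )
  new_harmonized(df, audit)
}

#' Retrieve the harmonization audit trail
#' @param x An `mr_harmonized` set (or an `mr_direction`).
#' @return A tibble with one row per input instrument.
#' @export
audit_log <- function(x) {
  if (inherits(x, "mr_direction")) return(x$audit)
  attr(x, "audit")
}
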