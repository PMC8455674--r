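# Reading, validating and writing GWAS summary-statistic and LD tables.

gwas_mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
gwas_optional  <- c("eaf", "n_cases", "n_controls", "n_total")
gwas_numeric   <- c("eaf", "beta", "se", "pvalue", "n_cases", "n_controls", "n_total")

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else if (grepl(",", first, fixed = TRUE)) "," else NULL
}

new_gwas_table <- function(records, trait_name, trait_type, provenance = NA_character_,
                           audit = list()) {
  out <- tibble::as_tibble(records)
  attr(out, "trait_name") <- trait_name
  attr(out, "trait_type") <- trait_type
  attr(out, "provenance") <- provenance
  attr(out, "audit") <- audit
  class(out) <- c("gwas_tbl", class(tibble::tibble()))
  out
}

#' Construct a GWAS summary-statistic table
#'
#' Wraps a data frame of per-variant association statistics as a `gwas_tbl`,
#' validating the core contract: unique rsIDs, positive standard errors,
#' p-values in (0, 1], and effect-allele frequencies (when present) in
#' \[0, 1\]. A p-value of exactly 0 (as printed by some GWAS) is floored to
#' the smallest positive double with a warning. Alleles are upper-cased.
#'
#' @param data Data frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue` and optionally `eaf`,
#'   `n_cases`, `n_controls`, `n_total`. `beta` is a log odds ratio for
#'   binary traits and a raw mean difference for continuous traits.
#' @param trait_name Trait label used in results.
#' @param trait_type `"binary"` (estimates later reported as odds ratios) or
#'   `"continuous"` (mean differences).
#' @param provenance Free-text source label.
#' @return A `gwas_tbl` tibble (one row per variant) carrying the trait
#'   metadata as attributes.
#' @export
gwas_table <- function(data, trait_name, trait_type = c("binary", "continuous"),
                       provenance = NA_character_) {
  trait_type <- match.arg(trait_type)
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(gwas_mandatory, names(data))
  if (length(missing_cols) > 0) {
    mr_abort(paste0("missing mandatory column(s): ", paste(missing_cols, collapse = ", ")),
             "mrkit_config_error")
  }
  for (col in setdiff(gwas_optional, names(data))) data[[col]] <- NA_real_
  data <- data[, c(gwas_mandatory, gwas_optional)]
  data$effect_allele <- toupper(data$effect_allele)
  data$other_allele <- toupper(data$other_allele)

  audit <- list()
  n0 <- nrow(data)
  keep <- !is.na(data$beta) & !is.na(data$se) & !is.na(data$pvalue) &
    data$se > 0 & !is.na(data$rsid)
  audit$dropped_unparseable <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) {
    mr_abort("no parseable records remain", "mrkit_input_error")
  }
  if (any(data$pvalue == 0)) {
    rlang::warn("p-values of exactly 0 floored to smallest positive double")
    data$pvalue[data$pvalue == 0] <- .Machine$double.xmin
  }
  if (any(data$pvalue < 0 | data$pvalue > 1)) {
    mr_abort("p-values must lie in (0, 1]", "mrkit_input_error")
  }
  if (any(!is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1))) {
    mr_abort("eaf must lie in [0, 1]", "mrkit_input_error")
  }
  # duplicate rsids: keep the record with the smallest p-value
  if (anyDuplicated(data$rsid)) {
    dup <- unique(data$rsid[duplicated(data$rsid)])
    audit$duplicate_rsids <- dup
    data <- data %>%
      dplyr::arrange(.data$pvalue) %>%
      dplyr::distinct(.data$rsid, .keep_all = TRUE)
    rlang::warn(paste0(length(dup), " duplicate rsid(s); kept smallest p-value"))
  }
  # Wald consistency: reported p should roughly match 2*pnorm(-|beta/se|)
  implied <- 2 * stats::pnorm(-abs(data$beta / data$se))
  ok <- implied < .Machine$double.xmin * 1e6 |
    abs(log10(pmax(data$pvalue, 1e-300)) - log10(pmax(implied, 1e-300))) < 1
  if (mean(ok) < 0.9) {
    rlang::warn("reported p-values inconsistent with |beta/se| Wald approximation for >10% of records")
  }
  audit$n_in <- n0
  audit$n_out <- nrow(data)
  new_gwas_table(data, trait_name, trait_type, provenance, audit)
}

#' Read a GWAS summary-statistic file
#'
#' Reads headered delimited text (tab or comma, auto-detected unless `delim`
#' is given), renames columns to the canonical scheme via `column_map`, and
#' validates through [gwas_table()]. Rows whose numeric fields fail to parse
#' are dropped and counted in the audit attribute.
#'
#' @param path File path.
#' @param trait_name,trait_type,provenance Passed to [gwas_table()].
#' @param column_map Named character vector mapping canonical field names
#'   (`rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n_cases`, `n_controls`, `n_total`) to source column names.
#'   Canonical names already present in the file need not be mapped.
#' @param delim Field delimiter; `NULL` auto-detects tab/comma.
#' @return A `gwas_tbl`.
#' @export
read_gwas <- function(path, trait_name, trait_type = c("binary", "continuous"),
                      column_map = NULL, delim = NULL, provenance = path) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) mr_abort(paste0("file not found: ", path), "mrkit_input_error")
  delim <- delim %||% detect_delim(path)
  if (is.null(delim)) mr_abort("could not infer delimiter (expected tab or comma)", "mrkit_config_error")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, col_types = readr::cols(.default = "c"))
  cmap <- as.list(column_map %||% character(0))
  for (canon in c(gwas_mandatory, gwas_optional)) {
    src <- cmap[[canon]] %||% canon
    if (src %in% names(raw)) {
      names(raw)[names(raw) == src] <- canon
    } else if (canon %in% gwas_mandatory) {
      mr_abort(paste0("column for mandatory field '", canon, "' (source name '", src,
                      "') not present in ", path), "mrkit_config_error")
    }
  }
  for (col in intersect(gwas_numeric, names(raw))) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  gwas_table(raw, trait_name = trait_name, trait_type = trait_type, provenance = provenance)
}

trait_type_of <- function(tbl, default = "binary") attr(tbl, "trait_type") %||% default
trait_name_of <- function(tbl, default = "trait") attr(tbl, "trait_name") %||% default

#' Apply the variant-level exclusion rules
#'
#' Removes records that are not simple biallelic SNPs: alleles must be single
#' bases in A/C/G/T, the two alleles must differ (indels and multi-base
#' alleles are excluded), and the identifier must be an rs number
#' (case-insensitive `rs` followed by digits). Idempotent.
#'
#' @param tbl A `gwas_tbl`.
#' @return The filtered `gwas_tbl`; per-rule drop counts are stored in the
#'   `"drop_counts"` attribute and appended to the audit.
#' @export
filter_variants <- function(tbl) {
  if (nrow(tbl) == 0) mr_abort("empty table", "mrkit_input_error")
  base_ok <- function(a) a %in% c("A", "C", "G", "T")
  biallelic <- base_ok(tbl$effect_allele) & base_ok(tbl$other_allele) &
    tbl$effect_allele != tbl$other_allele
  has_rsid <- grepl("^rs[0-9]+$", tbl$rsid, ignore.case = TRUE)
  drops <- c(
    non_biallelic_or_indel = sum(!biallelic),
    no_rs_number = sum(biallelic & !has_rsid)
  )
  out <- tbl[biallelic & has_rsid, , drop = FALSE]
  audit <- attr(tbl, "audit") %||% list()
  audit$variant_filter <- as.list(drops)
  attr(out, "audit") <- audit
  attr(out, "drop_counts") <- drops
  attr(out, "trait_name") <- attr(tbl, "trait_name")
  attr(out, "trait_type") <- attr(tbl, "trait_type")
  attr(out, "provenance") <- attr(tbl, "provenance")
  class(out) <- class(tbl)
  out
}

#' Construct a pairwise LD table
#'
#' Holds pairwise r-squared between variants. Pairs are stored in canonical
#' (sorted) order; an absent pair is treated as r2 = 0 and a self pair as 1.
#'
#' @param pairs Data frame with columns `rsid_a`, `rsid_b`, `r2`.
#' @return An `ld_tbl` tibble.
#' @export
ld_table <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("rsid_a", "rsid_b", "r2")
  if (!all(need %in% names(pairs))) {
    mr_abort("LD table needs columns rsid_a, rsid_b, r2", "mrkit_config_error")
  }
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(is.na(pairs$r2)) || any(pairs$r2 < 0 | pairs$r2 > 1)) {
    mr_abort("r2 values must lie in [0, 1]", "mrkit_input_error")
  }
  a <- pmin(pairs$rsid_a, pairs$rsid_b)
  b <- pmax(pairs$rsid_a, pairs$rsid_b)
  out <- tibble::tibble(rsid_a = a, rsid_b = b, r2 = pairs$r2)
  out <- out[out$rsid_a != out$rsid_b, , drop = FALSE]
  key <- paste(out$rsid_a, out$rsid_b)
  if (anyDuplicated(key)) {
    agg <- tapply(out$r2, key, function(x) diff(range(x)))
    if (any(agg > 1e-12)) {
      mr_abort("conflicting r2 values for the same variant pair", "mrkit_input_error")
    }
    out <- out[!duplicated(key), , drop = FALSE]
  }
  class(out) <- c("ld_tbl", class(tibble::tibble()))
  out
}

#' Read a three-column LD table
#'
#' @param path Delimited text file with columns `rsid_a`, `rsid_b`, `r2`.
#' @param delim Delimiter; `NULL` auto-detects tab/comma.
#' @return An `ld_tbl`.
#' @export
read_ld <- function(path, delim = NULL) {
  if (!file.exists(path)) mr_abort(paste0("file not found: ", path), "mrkit_input_error")
  delim <- delim %||% detect_delim(path)
  if (is.null(delim)) mr_abort("could not infer delimiter", "mrkit_config_error")
  ld_table(readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE))
}

#' Look up pairwise r-squared
#'
#' Vectorised over `a` and `b`; self pairs return 1, absent pairs 0.
#'
#' @param ld An `ld_tbl` (or `NULL`, meaning no LD anywhere).
#' @param a,b Character vectors of rsIDs (recycled to common length).
#' @return Numeric vector of r2 values.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- as.numeric(a == b)
  if (!is.null(ld) && nrow(ld) > 0) {
    idx <- stats::setNames(ld$r2, paste(ld$rsid_a, ld$rsid_b))
    key <- paste(pmin(a, b), pmax(a, b))
    hit <- !is.na(idx[key]) & a != b
    out[hit] <- idx[key[hit]]
  }
  out
}

#' Write an MR results table
#'
#' Writes a tidy results tibble (as produced by [tidy()] on a direction,
#' battery or screen object) to tab-delimited text at full precision, so a
#' write/read cycle preserves estimates well beyond 6 significant digits.
#'
#' @param results Non-empty data frame of results rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    mr_abort("results collection is empty", "mrkit_input_error")
  }
  readr::write_tsv(tibble::as_tibble(results), path)
  invisible(path)
}

#' Read back a results table written by [write_mr_results()]
#' @param path File path.
#' @return A tibble.
#' @export
read_mr_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write an audit trail as JSON
#'
#' @param audit List or data frame of per-stage drop/flip records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_json <- function(audit, path) {
  jsonlite::write_json(audit, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "string")
  invisible(path)
}
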