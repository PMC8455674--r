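# broom-style tidy()/glance() methods and print methods.

method_labels <- c(ivw = "IVW", weighted_median = "Weighted median",
                   egger = "MR-Egger", presso = "MR-PRESSO", wald = "Wald ratio")

#' @export
tidy.mr_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    estimate = x$estimate,
    std_error = x$std_error,
    conf_low = x$conf_low,
    conf_high = x$conf_high,
    p_value = x$p_value,
    n_snp = x$n_snp
  )
}

#' @export
glance.mr_estimate <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_snp = x$n_snp,
    q_stat = x$q_stat %||% NA_real_,
    q_pvalue = x$q_pvalue %||% NA_real_,
    egger_intercept = x$egger_intercept %||% NA_real_,
    egger_intercept_pvalue = x$egger_intercept_pvalue %||% NA_real_,
    i2_gx = x$i2_gx %||% NA_real_,
    phi2 = x$phi2 %||% NA_real_
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<%s> beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g, J = %d\n",
              method_labels[[x$method]] %||% x$method, x$estimate, x$std_error,
              x$conf_low, x$conf_high, x$p_value, x$n_snp))
  invisible(x)
}

#' @export
tidy.mr_presso <- function(x, ...) {
  t <- tidy.mr_estimate(x$corrected)
  t$method <- "presso"
  t$n_snp <- x$corrected$n_snp
  t
}

#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(
    global_rss = x$global_rss,
    global_pvalue = x$global_pvalue,
    n_outliers = length(x$outlier_rsids),
    distortion_pvalue = x$distortion_pvalue,
    n_sim = x$n_sim,
    seed = x$seed
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("<MR-PRESSO> global RSS = %.4g, global p = %.3g, %d outlier(s)%s\n",
              x$global_rss, x$global_pvalue, length(x$outlier_rsids),
              if (length(x$outlier_rsids) > 0)
                paste0(": ", paste(x$outlier_rsids, collapse = ", ")) else ""))
  if (!is.null(x$corrected)) {
    cat("corrected "); print(x$corrected)
  }
  invisible(x)
}

# assemble per-method rows on the reporting scale of the outcome trait
battery_rows <- function(battery) {
  rows <- purrr::compact(purrr::map(battery$estimates, function(e) {
    if (is.null(e)) NULL else dplyr::left_join(tidy(e), glance(e),
                                               by = c("method", "n_snp"))
  }))
  if (!is.null(battery$presso)) {
    pres <- dplyr::left_join(tidy(battery$presso), tibble::tibble(
      method = "presso",
      q_stat = NA_real_, q_pvalue = NA_real_,
      egger_intercept = NA_real_, egger_intercept_pvalue = NA_real_,
      i2_gx = NA_real_, phi2 = NA_real_
    ), by = "method")
    rows <- c(rows, list(pres))
  }
  out <- dplyr::bind_rows(rows)
  if (battery$trait_type == "binary") {
    out <- out %>% dplyr::mutate(
      scale = "odds_ratio",
      estimate_exp = exp(.data$estimate),
      conf_low_exp = exp(.data$conf_low),
      conf_high_exp = exp(.data$conf_high)
    )
  } else {
    out <- out %>% dplyr::mutate(
      scale = "mean_difference",
      estimate_exp = NA_real_, conf_low_exp = NA_real_, conf_high_exp = NA_real_
    )
  }
  out
}

#' @export
tidy.mr_battery <- function(x, ...) battery_rows(x)

#' @export
glance.mr_battery <- function(x, ...) {
  tibble::tibble(n_snp = x$n_snp, trait_type = x$trait_type,
                 n_methods = sum(!purrr::map_lgl(x$estimates, is.null)) +
                   as.integer(!is.null(x$presso)))
}

#' Tidy a direction result into the per-method results table
#'
#' One row per estimator with the estimate on both the log/beta scale and
#' the reporting scale (odds ratio for binary outcomes, mean difference for
#' continuous), heterogeneity and pleiotropy diagnostics, and direction
#' metadata.
#'
#' @param x An `mr_direction`.
#' @param ... Unused.
#' @export
tidy.mr_direction <- function(x, ...) {
  battery_rows(x$battery) %>%
    dplyr::mutate(exposure = x$exposure, outcome = x$outcome,
                  f_statistic = x$f_statistic, .before = 1)
}

#' @export
glance.mr_direction <- function(x, ...) {
  ivw <- x$battery$estimates$ivw
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome, trait_type = x$trait_type,
    n_snp = x$n_snp, f_statistic = x$f_statistic,
    ivw_estimate = ivw$estimate, ivw_p = ivw$p_value,
    q_stat = ivw$q_stat, q_pvalue = ivw$q_pvalue,
    n_presso_outliers = if (is.null(x$presso)) NA_integer_ else length(x$presso$outlier_rsids),
    significance_tier = x$significance_tier,
    has_sensitivity = !is.null(x$sensitivity)
  )
}

#' @export
print.mr_direction <- function(x, ...) {
  cat(sprintf("<mr_direction> %s -> %s (J = %d, mean F = %.1f, tier = %s)\n",
              x$exposure, x$outcome, x$n_snp, x$f_statistic, x$significance_tier))
  print(tidy(x)[, c("method", "estimate", "conf_low", "conf_high", "p_value")])
  invisible(x)
}

#' @export
tidy.mr_screen <- function(x, ...) {
  purrr::imap(unclass(x), function(d, nm) {
    tidy(d) %>% dplyr::mutate(confounder = nm, .before = 1)
  }) %>% dplyr::bind_rows()
}

#' @export
glance.mr_screen <- function(x, ...) {
  purrr::map(unclass(x), glance) %>% dplyr::bind_rows()
}
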