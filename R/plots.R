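# ggplot2 visualisations: per-variant scatter with fitted estimators,
# forest plots of method batteries and confounder screens.

#' Scatter plot of a harmonized instrument set
#'
#' Per-variant exposure vs outcome associations with one fitted line per
#' estimator (IVW through the origin, MR-Egger with intercept); variants
#' are oriented so the exposure association is positive, matching the
#' Egger parametrisation.
#'
#' @param object An `mr_harmonized` set.
#' @param seed Seed for the weighted-median fit shown in the legend lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_harmonized <- function(object, seed = 1L, ...) {
  flip <- sign(object$beta_exposure)
  flip[flip == 0] <- 1
  df <- tibble::tibble(
    x = object$beta_exposure * flip, y = object$beta_outcome * flip,
    xmin = object$beta_exposure * flip - 1.96 * object$se_exposure,
    xmax = object$beta_exposure * flip + 1.96 * object$se_exposure,
    ymin = object$beta_outcome * flip - 1.96 * object$se_outcome,
    ymax = object$beta_outcome * flip + 1.96 * object$se_outcome
  )
  ivw <- mr_ivw(object)
  lines <- tibble::tibble(method = "IVW", intercept = 0, slope = ivw$estimate)
  if (nrow(object) >= 3) {
    egg <- mr_egger(object)
    lines <- dplyr::bind_rows(lines, tibble::tibble(
      method = "MR-Egger", intercept = egg$egger_intercept, slope = egg$estimate))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                           linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
                            linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_abline(data = lines,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope,
                                      colour = .data$method)) +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

forest_plot <- function(rows, y) {
  binary <- all(rows$scale == "odds_ratio")
  if (binary) {
    rows$est <- rows$estimate_exp
    rows$lo <- rows$conf_low_exp
    rows$hi <- rows$conf_high_exp
    ref <- 1
    xlab <- "Odds ratio (95% CI)"
  } else {
    rows$est <- rows$estimate
    rows$lo <- rows$conf_low
    rows$hi <- rows$conf_high
    ref <- 0
    xlab <- "Mean difference (95% CI)"
  }
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$est, y = .data[[y]])) +
    ggplot2::geom_vline(xintercept = ref, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
  if (binary) p <- p + ggplot2::scale_x_log10()
  p
}

#' Forest plot of one direction's estimator battery
#'
#' @param object An `mr_direction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_direction <- function(object, ...) {
  rows <- tidy(object)
  rows$label <- unname(method_labels[rows$method])
  forest_plot(rows, "label") +
    ggplot2::ggtitle(paste(object$exposure, "→", object$outcome))
}

#' Forest plot of a confounder screen (IVW rows)
#'
#' @param object An `mr_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mr_screen <- function(object, ...) {
  rows <- tidy(object) %>% dplyr::filter(.data$method == "ivw")
  forest_plot(rows, "confounder") +
    ggplot2::ggtitle("Genetic predictors of the exposure vs candidate confounders")
}
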