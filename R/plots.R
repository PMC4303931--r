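#' Coefficient (forest-style) plot for a fitted meta-regression
#'
#' @param object A `"psf_hblm"` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psf_hblm <- function(object, ...) {
  tab <- tidy(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lower,
                                         xmax = .data$ci_upper),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "estimate (Hedges' d scale)", y = NULL,
                  title = paste0(object$model_tag, " model, ",
                                 format(100 * object$level),
                                 "% credible intervals")) +
    ggplot2::theme_minimal()
}

#' Effect size against phylogenetic distance with the fitted regression line
#'
#' Points are the observed effects (sized by precision); the line and ribbon
#' are the fitted intercept + distance slope with pointwise intervals from
#' the coefficient covariance.
#'
#' @param dataset A [meta_dataset()] whose design includes `phylo_distance`.
#' @param fit A `"psf_hblm"` fit of that dataset.
#' @return A ggplot.
#' @export
plot_regression <- function(dataset, fit) {
  stopifnot("phylo_distance" %in% colnames(dataset$X))
  pts <- tibble::tibble(pd = dataset$X[, "phylo_distance"], d = dataset$d,
                        se = sqrt(diag(dataset$V)))
  sel <- match(c("intercept", "phylo_distance"), fit$beta$term)
  b <- fit$beta$estimate[sel]
  Cv <- fit$cov_beta[sel, sel]
  grid <- seq(min(pts$pd), max(pts$pd), length.out = 100)
  Xg <- cbind(1, grid)
  pred <- drop(Xg %*% b)
  pse <- sqrt(rowSums((Xg %*% Cv) * Xg))
  tq <- stats::qt((1 + fit$level) / 2, df = fit$df)
  band <- tibble::tibble(pd = grid, fit = pred,
                         lo = pred - tq * pse, hi = pred + tq * pse)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$pd)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$d, size = 1 / .data$se),
                        alpha = 0.5, show.legend = FALSE) +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(x = "phylogenetic distance (My)", y = "Hedges' d") +
    ggplot2::theme_minimal()
}

#' Funnel plot
#'
#' Standard error (inverted axis) against effect size; imputed trim-and-fill
#' studies, if supplied, are shown as open points.
#'
#' @param funnel A tibble from [funnel_data()].
#' @param trimfill Optional `"psf_trimfill"` result whose imputed values are
#'   overlaid.
#' @return A ggplot.
#' @export
plot_funnel <- function(funnel, trimfill = NULL) {
  p <- ggplot2::ggplot(funnel, ggplot2::aes(x = .data$d, y = .data$se)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Hedges' d", y = "standard error") +
    ggplot2::theme_minimal()
  if (!is.null(trimfill)) {
    p <- p + ggplot2::geom_vline(xintercept = trimfill$adjusted_mean,
                                 linetype = 2)
    if (nrow(trimfill$filled)) {
      imp <- tibble::tibble(d = trimfill$filled$d,
                            se = sqrt(trimfill$filled$var))
      p <- p + ggplot2::geom_point(data = imp, shape = 1, colour = "red")
    }
  }
  p
}

#' Cumulative meta-analysis trajectory
#'
#' @param object A `"psf_cumulative"` tibble from [cumulative_meta()].
#' @param ... Unused.
#' @return A ggplot of the tracked coefficient against the number of
#'   included (most precise first) effect sizes.
#' @export
autoplot.psf_cumulative <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$n_included, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "effect sizes included (most precise first)",
                  y = attr(object, "term")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
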