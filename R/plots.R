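#' Q-Q plot of burden p-values
#'
#' Expected vs observed p-value quantiles on the -log10 scale, one panel
#' per disease. Under a well-calibrated background model the points lie on
#' the diagonal, with true hotspots departing upward at the right.
#'
#' @param object A `burden_result` tibble from [burden_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_result
#' @export
autoplot.burden_result <- function(object, ...) {
  dat <- object %>%
    dplyr::group_by(.data$disease) %>%
    dplyr::reframe(qq_table(.data$p))
  ggplot2::ggplot(dat, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$disease)) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_bw()
}

#' Empirical CDF of the overdispersion KS statistics
#'
#' @param object A `ks_report` from [ks_overdispersion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ks_report
#' @export
autoplot.ks_report <- function(object, ...) {
  ggplot2::ggplot(object$statistics, ggplot2::aes(.data$statistic)) +
    ggplot2::stat_ecdf() +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "two-sample KS statistic (observed vs constant-rate)",
                  y = "empirical CDF") +
    ggplot2::theme_bw()
}

#' Cumulative explained variance of the covariate PCA
#'
#' @param object A `covariate_pca` from [fit_pca()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot covariate_pca
#' @export
autoplot.covariate_pca <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$pc, .data$cumulative)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "principal component",
                  y = "cumulative proportion of variance") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
}

#' Observed vs predicted per-bin mutation counts
#'
#' Scatter of training counts against fitted background means, annotated
#' with the Pearson correlation — the standard visual check of regression
#' performance.
#'
#' @param object An `nb_regression` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nb_regression
#' @export
autoplot.nb_regression <- function(object, ...) {
  r <- stats::cor(object$y, object$fitted)
  ggplot2::ggplot(tibble::tibble(observed = object$y,
                                 predicted = object$fitted),
                  ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::labs(x = "predicted mean", y = "observed count",
                  subtitle = sprintf("Pearson r = %.3f", r)) +
    ggplot2::theme_bw()
}
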