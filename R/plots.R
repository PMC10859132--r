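# ggplot2 renderings of the diagnostic data. The plot DATA (scatter_data,
# zip_plot_data) is the contract; these are thin layers over it.

#' Plot standard error against point estimate
#'
#' One panel per dgm-method cell; outliers (huge or zero standard errors,
#' implausible estimates) stand out immediately.
#'
#' @param estimates An estimates tibble or `sim_study`.
#' @return A ggplot object.
#' @export
plot_scatter <- function(estimates) {
  dat <- scatter_data(estimates)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$se)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_grid(dgm ~ method, scales = "free") +
    ggplot2::labs(x = "point estimate (log odds ratio)",
                  y = "standard error estimate") +
    ggplot2::theme_bw()
}

#' Zip plot of confidence intervals
#'
#' Intervals stacked in order of their Wald p-value against the true
#' value (least compatible at the bottom), coloured by coverage. Bias
#' shows as non-covering intervals piling up on one side of the truth;
#' too-narrow intervals show as symmetric non-coverage.
#'
#' @param estimates An estimates tibble or `sim_study`.
#' @param theta True estimand value (drawn as a vertical line).
#' @return A ggplot object.
#' @export
plot_zip <- function(estimates, theta = 0) {
  dat <- zip_plot_data(estimates, theta = theta)
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$rank_fraction)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$ci_low, xend = .data$ci_high,
                   yend = .data$rank_fraction, colour = .data$covers),
      linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = theta, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "grey60", `FALSE` = "red3"), name = "covers") +
    ggplot2::facet_grid(dgm ~ method) +
    ggplot2::labs(x = "95% confidence interval",
                  y = "rank by p-value (fraction)") +
    ggplot2::theme_bw()
}

#' @rdname plot_zip
#' @param object A `sim_study`.
#' @param ... Passed to [plot_zip()].
#' @exportS3Method ggplot2::autoplot
autoplot.sim_study <- function(object, ...) plot_zip(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
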