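# ggplot2 convenience views of the result tables. All analysis output is
# tabular; these plots are display helpers and nothing downstream depends
# on them.

#' Forest plot of reporting odds ratios
#'
#' @param signals Tibble from [disproportionality()] (or a subgroup result
#'   with `adj_ror` renamed to `ror`).
#' @param log_x Use a log10 x axis.
#' @return A ggplot object.
#' @export
plot_signal_forest <- function(signals, log_x = TRUE) {
  df <- signals |>
    dplyr::arrange(.data$ror) |>
    dplyr::mutate(event = factor(.data$event, levels = .data$event))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ror, y = .data$event)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_lo, xmax = .data$ror_hi), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$positive_any)) +
    ggplot2::labs(x = "Reporting odds ratio (95% CI)", y = NULL,
                  colour = "positive") +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Volcano plot of subgroup comparisons
#'
#' Log2 of the stratified ROR against -log10 of the FDR-adjusted p-value.
#'
#' @param subgroup Tibble from [subgroup_ror()].
#' @param p_cut Significance threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_subgroup_volcano <- function(subgroup, p_cut = 0.05) {
  ggplot2::ggplot(
    subgroup,
    ggplot2::aes(x = log2(.data$adj_ror), y = -log10(.data$p_adj))) +
    ggplot2::geom_hline(yintercept = -log10(p_cut), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_adj < p_cut)) +
    ggplot2::labs(x = "log2 stratified ROR (target vs control)",
                  y = "-log10 adjusted p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Onset-time histogram with the fitted Weibull density
#'
#' @param tto_days Integer vector or the tibble from [extract_tto()].
#' @param fit Optional `weibull_fit` overlay.
#' @param binwidth Histogram bin width in days.
#' @return A ggplot object.
#' @export
plot_tto <- function(tto_days, fit = NULL, binwidth = 15) {
  if (is.data.frame(tto_days)) tto_days <- tto_days$tto_days
  df <- tibble(tto = tto_days)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tto)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      binwidth = binwidth, boundary = 0, fill = "grey70", colour = "white") +
    ggplot2::labs(x = "Time to onset (days)", y = "Density") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::stat_function(
      fun = stats::dweibull,
      args = list(shape = fit$shape, scale = fit$scale), colour = "firebrick")
  }
  p
}

#' @rdname plot_tto
#' @param object A `weibull_fit` object.
#' @param ... Passed to [plot_tto()] (requires `tto_days`).
#' @export
autoplot.weibull_fit <- function(object, tto_days, ...) {
  plot_tto(tto_days, fit = object, ...)
}

#' Cumulative-incidence curve of onset
#'
#' @inheritParams plot_tto
#' @return A ggplot object (step curve of the empirical CDF).
#' @export
plot_tto_cumulative <- function(tto_days) {
  df <- tto_ecdf(tto_days)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$cum_frac)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Days since treatment start",
                  y = "Cumulative fraction of onset reports") +
    ggplot2::theme_minimal()
}
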