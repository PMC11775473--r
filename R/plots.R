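#' Plot a pathway-result P-value distribution
#'
#' Histogram of the combined P-values across pathways, with the 0.05
#' threshold marked — the per-dataset analogue of a P-value distribution
#' panel.
#'
#' @param object A `pea_results` tibble from [run_pea()].
#' @param bins Histogram bins.
#' @param ... Unused.
#' @export
autoplot.pea_results <- function(object, bins = 20, ...) {
  d <- dplyr::filter(object, !is.na(.data$pvalue_combined))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pvalue_combined)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = 0.05, linetype = 2, colour = "red") +
    ggplot2::labs(x = "combined P-value", y = "pathways") +
    ggplot2::theme_minimal()
}

#' Plot Type I error and power against sample size
#'
#' Line plots of the two error rates versus per-group sample size, one
#' panel per rate and SNR, coloured by method — the axes of the standard
#' Type-I/power comparison figure.
#'
#' @param summary Tibble from
#'   `type_i_and_power(records, by = c("n", "snr", "method"))`.
#' @export
plot_error_power <- function(summary) {
  long <- tidyr::pivot_longer(summary, c("type_i", "power"),
                              names_to = "rate", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$n, y = .data$value,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_grid(rate ~ snr,
                        labeller = ggplot2::label_both) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "samples per group", y = "rate") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
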