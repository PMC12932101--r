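#' Plot normalized transduction curves
#'
#' Transduction efficiency (%) against the two-fold dilution series, one
#' colour per sample, solid/dashed by assay format, with the 50%
#' neutralization threshold marked. The x axis runs from the most dilute
#' serum (left) to the strongest tested dilution (right), titer-labelled.
#'
#' @param curves Curve points from [normalize_plate()].
#' @param threshold Horizontal reference line, default 50 (%).
#' @return A ggplot object.
#' @export
plot_curves <- function(curves, threshold = 50) {
  stopifnot(is.data.frame(curves))
  dil <- sort(unique(curves$dilution))
  p <- ggplot2::ggplot(
    curves,
    ggplot2::aes(x = log2(.data$dilution), y = .data$transduction_pct,
                 colour = .data$sample_id, linetype = .data$format)
  ) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_continuous(breaks = log2(dil),
                                labels = dilution_label(dil)) +
    ggplot2::labs(x = "Serum dilution", y = "Transduction efficiency (%)",
                  colour = "Sample", linetype = "Format") +
    ggplot2::theme_minimal()
  if (all(c("sd_pct", "n") %in% names(curves))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$transduction_pct - .data$sd_pct,
                   ymax = .data$transduction_pct + .data$sd_pct),
      width = 0.15
    )
  }
  if (length(unique(curves$serotype)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$serotype))
  }
  p
}

#' @describeIn plot_curves `autoplot` method for a Hill fit: the data
#'   points, the posterior-median curve, and (when not censored) the ND50
#'   with its 95% credible interval.
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  xr <- range(log2(object$data$dilution))
  grid <- tibble::tibble(x = seq(xr[1] - 0.5, xr[2] + 0.5, length.out = 200))
  grid$y <- hill_median_curve(object, grid$x)
  dil <- sort(unique(object$data$dilution))
  s <- hill_nd50(object)
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = log2(.data$dilution),
                                    y = .data$transduction_pct)) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dotted",
                        colour = "grey40") +
    ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = log2(dil),
                                labels = dilution_label(dil)) +
    ggplot2::labs(x = "Serum dilution", y = "Transduction efficiency (%)") +
    ggplot2::theme_minimal()
  if (!s$censored) {
    p <- p +
      ggplot2::annotate("segment", x = log2(s$ci_low), xend = log2(s$ci_high),
                        y = 50, yend = 50, colour = "firebrick",
                        linewidth = 1) +
      ggplot2::annotate("segment", x = log2(s$nd50), xend = log2(s$nd50),
                        y = 60, yend = 51, colour = "firebrick",
                        linetype = "dashed",
                        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")))
  }
  p
}
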