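#' Plot coverage-efficiency curves
#'
#' Coverage rate against sequencing effort, one line per depth threshold --
#' the standard view for reading off how much sequencing a kit needs to
#' reach, say, 90% of target bases at 30X.
#'
#' @param grid An effort grid (columns `effort`, `depth`, `rate`).
#' @param required_rate Optional horizontal reference line (e.g. 0.90).
#' @return A ggplot object.
#' @export
plot_effort_curves <- function(grid, required_rate = NULL) {
  p <- ggplot2::ggplot(
    grid,
    ggplot2::aes(
      x = .data$effort, y = .data$rate,
      colour = factor(.data$depth), group = factor(.data$depth)
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(
      x = "sequencing effort (read pairs)",
      y = "target bases covered",
      colour = "depth (X)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(required_rate)) {
    p <- p + ggplot2::geom_hline(
      yintercept = required_rate, linetype = "dashed"
    )
  }
  p
}

#' @method autoplot coverage_profile
#' @export
autoplot.coverage_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$depth)) +
    ggplot2::geom_histogram(bins = 50, boundary = 0) +
    ggplot2::geom_vline(
      xintercept = mean(d$depth), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "depth (X)", y = "target bases",
      title = "Per-base coverage distribution"
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot kit_comparison
#' @export
autoplot.kit_comparison <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(
    tab,
    ggplot2::aes(x = factor(.data$effort), y = .data$value, fill = .data$kit)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sequencing effort", y = NULL, fill = "kit") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
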