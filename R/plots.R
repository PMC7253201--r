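#' Scatter of two estimate sets with the through-origin fit
#'
#' Generic building block for the package's comparison figures: paired
#' estimates (branch lengths, node ages, distances) from a simple and a
#' complex model, the 1:1 line (dashed) and the fitted through-origin line,
#' annotated with slope and R-squared.
#'
#' @param x,y Paired estimates (complex on x, simple on y).
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_through_origin <- function(x, y, xlab = "complex model",
                                ylab = "simple model") {
  f <- regression_through_origin(x, y)
  df <- tibble(x = x, y = y)
  lim <- max(c(x, y), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_abline(slope = f$slope, intercept = 0, colour = "#2c7fb8") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0, lim), ylim = c(0, lim)) +
    ggplot2::labs(
      x = xlab, y = ylab,
      subtitle = sprintf("slope = %.3f, R² = %.3f (n = %d)",
                         f$slope, f$r_squared, f$n)) +
    ggplot2::theme_minimal()
}

#' @describeIn comparison_report Branch-length scatter for a comparison report.
#' @param object A `relchron_report`.
#' @param ... Unused.
#' @method autoplot relchron_report
#' @export
autoplot.relchron_report <- function(object, ...) {
  td <- tidy(object)
  strat <- td[td$stratum != "all" & td$statistic == "branch_length_slope", ]
  ggplot2::ggplot(strat, ggplot2::aes(x = .data$stratum, y = .data$value)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "branch category (complex-model tree)",
      y = "through-origin slope (simple vs complex)",
      title = sprintf("%s vs %s", object$models[["simple"]],
                      object$models[["complex"]])) +
    ggplot2::theme_minimal()
}

#' @describeIn subsampling_experiment Dispersion-vs-size boxplot, one panel per
#'   model (the classic shrinking-spread figure).
#' @param object A tibble from [subsampling_experiment()].
#' @param ... Unused.
#' @method autoplot relchron_subsampling
#' @export
autoplot.relchron_subsampling <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$size), y = .data$r_squared)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "#a6bddb") +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "ingroup sequences sampled",
                  y = expression(R^2 ~ "of branch lengths vs reference")) +
    ggplot2::theme_minimal()
}

#' Chronogram age comparison plot
#'
#' Normalized internal-node ages of two chronograms against each other.
#'
#' @param chron_simple,chron_complex Two [relative_times()] results on the
#'   same topology.
#' @return A ggplot object.
#' @export
plot_age_comparison <- function(chron_simple, chron_complex) {
  plot_through_origin(internal_ages(chron_complex), internal_ages(chron_simple),
                      xlab = "relative node age (complex model)",
                      ylab = "relative node age (simple model)")
}
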