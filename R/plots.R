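#' Plot a nutrient's piecewise score chart
#'
#' Draws the trapezoid (adequacy) or plateau-then-decline (moderation) score
#' shape for one nutrient's breakpoints, the chart users consult to see why
#' an intake scored as it did.
#'
#' @param breakpoints A breakpoints tibble from [derive_breakpoints()].
#' @param nutrient Which nutrient to draw (default: the first row).
#' @return A ggplot object.
#' @export
plot_score_chart <- function(breakpoints, nutrient = breakpoints$nutrient[1]) {
  bp <- breakpoints[breakpoints$nutrient == nutrient, ]
  stopifnot(nrow(bp) == 1)
  if (bp$shape == "adequacy") {
    xs <- c(0, bp$a, bp$b, bp$c, bp$d, bp$d * 1.15)
    ys <- c(0, 0, 1, 1, 0, 0)
  } else {
    xs <- c(0, bp$b, bp$c, bp$c * 1.3)
    ys <- c(1, 1, 0, 0)
  }
  unit <- if (bp$pct_energy) "% of energy" else "amount"
  ggplot2::ggplot(tibble::tibble(x = xs, y = ys),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = sprintf("%s (%s)", nutrient, unit), y = "score",
                  title = sprintf("Score chart: %s (%s)", nutrient,
                                  bp$shape)) +
    ggplot2::theme_minimal()
}

#' Percent-of-reference scatter for a period
#'
#' Dot plot of each nutrient's mean intake as percent of its reference
#' anchor, with guides at 100% and at the upper healthy-range multiple.
#'
#' @param profile_tbl Output of [percent_dri_profile()].
#' @return A ggplot object.
#' @export
plot_percent_dri <- function(profile_tbl) {
  ggplot2::ggplot(profile_tbl,
                  ggplot2::aes(x = .data$pct_of_reference,
                               y = stats::reorder(.data$nutrient,
                                                  .data$pct_of_reference))) +
    ggplot2::geom_vline(xintercept = c(100, 200), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$anchor_type), size = 2) +
    ggplot2::labs(x = "% of reference anchor", y = NULL,
                  colour = "anchor") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' @param object A `dq_bland_altman` result.
#' @param ... Ignored.
#' @return A ggplot object with bias and limits of agreement.
#' @method autoplot dq_bland_altman
#' @export
autoplot.dq_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean of the two scores", y = "difference",
                  title = sprintf("Bias %.2f, LoA [%.2f, %.2f], %.1f%% within",
                                  object$bias, object$loa_low,
                                  object$loa_high, object$pct_within)) +
    ggplot2::theme_minimal()
}

#' Scree plot of variance explained
#'
#' @param object A `dq_pca` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot dq_pca
#' @export
autoplot.dq_pca <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$component, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative), colour = "grey30") +
    ggplot2::labs(x = "principal component",
                  y = "proportion of variance (bars) / cumulative (line)") +
    ggplot2::theme_minimal()
}

#' Group means across strata
#'
#' @param object A `dq_strata` result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot dq_strata
#' @export
autoplot.dq_strata <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = factor(.data$group), y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "quantile group of the stratifying score",
                  y = "mean of compared values",
                  title = sprintf("Kruskal-Wallis p = %.3g", object$p_value)) +
    ggplot2::theme_minimal()
}
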