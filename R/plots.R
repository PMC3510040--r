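#' Plot called ROHs along the genome
#'
#' One horizontal track per chromosome; ROHs drawn as segments coloured by
#' size class, over the per-bin snpbin values in grey when `bins` is given.
#'
#' @param object A `roh_calls` object.
#' @param bins Optional bin grid to show the underlying snpbin signal.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roh_calls
#' @export
autoplot.roh_calls <- function(object, bins = NULL, ...) {
  r <- object$rohs
  p <- ggplot2::ggplot()
  if (!is.null(bins)) {
    b <- as_tibble(bins)[bins$covered, ]
    p <- p + ggplot2::geom_line(
      data = b,
      ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2e6,
                   y = .data$snpbin),
      colour = "grey70", linewidth = 0.2)
  }
  if (nrow(r) > 0) {
    p <- p + ggplot2::geom_segment(
      data = r,
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = -1, yend = -1, colour = .data$size_class),
      linewidth = 3)
  }
  p +
    ggplot2::facet_wrap(~chrom, ncol = 1, strip.position = "right") +
    ggplot2::labs(x = "position (Mb)", y = "snpbin (SNPs / 10 kb covered)",
                  colour = "ROH class",
                  title = sprintf("ROH calls: %s", object$individual_id)) +
    ggplot2::theme_minimal()
}

#' Plot a landscape profile over relative chromosomal position
#'
#' @param profile Profile tibble with `rel_lower, rel_upper` and a `value`
#'   or `density` column ([relative_profile()],
#'   [roh_positional_distribution()], ...).
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, ylab = "value") {
  col <- intersect(c("value", "density"), names(profile))[1]
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = (.data$rel_lower + .data$rel_upper) / 2,
                               y = .data[[col]])) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "relative chromosomal position", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot the permutation calibration
#'
#' Observed (red) and permuted (blue) candidate stretches as length versus
#' relative mean snpbin, with the relative threshold marked.
#'
#' @param object A `roh_calibration` from [permutation_calibration()].
#' @param rel_threshold Vertical reference line (default 0.25).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roh_calibration
#' @export
autoplot.roh_calibration <- function(object, rel_threshold = 0.25, ...) {
  s <- object$stretches
  s$which <- ifelse(s$rep == 0, "observed", "permuted")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$rel_mean, y = .data$length_bins,
                                  colour = .data$which)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = rel_threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(observed = "red3",
                                            permuted = "steelblue")) +
    ggplot2::labs(x = "stretch mean snpbin / genomic average",
                  y = "stretch length (bins)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the sequence-versus-array comparison
#'
#' @param object A `method_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(object, ...) {
  d <- object$by_individual
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cum_seq_bp / 1e6,
                                  y = .data$cum_array_bp / 1e6,
                                  shape = .data$excluded)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(data = d[!d$excluded, ], method = "lm",
                         formula = y ~ x, se = FALSE, linewidth = 0.5) +
    ggplot2::labs(x = "sequence-based cumulative ROH (Mb)",
                  y = "array-based cumulative ROH (Mb)",
                  title = sprintf("R² = %.3f",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}
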