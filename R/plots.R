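#' Genome scan plot of windowed FST
#'
#' One panel per chromosome, with the 0.998 quantile drawn as a dashed line
#' and peak-member windows (FST at or above it) highlighted.
#'
#' @param object An `fst_windows` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fst_windows <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[!is.na(d$fst), ]
  q998 <- quantile(d$fst, 0.998, type = 7, names = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                  y = .data$fst)) +
    ggplot2::geom_point(size = 0.4, colour = "grey40") +
    ggplot2::geom_point(data = d[d$fst >= q998, ], colour = "maroon", size = 0.8) +
    ggplot2::geom_hline(yintercept = q998, linetype = "dashed", colour = "goldenrod") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(F[ST])) +
    ggplot2::theme_minimal()
}

#' Cumulative GC-score track with detected pericentromeric regions
#'
#' @param object A `gc_windows` tibble.
#' @param regions Optional output of [detect_pericentromere()] to shade.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gc_windows <- function(object, regions = NULL, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$start / 1e6, y = .data$cum)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "cumulative low-GC score") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "grey70", alpha = 0.4
    )
  }
  p
}

#' Histogram of the simulated null FST distribution
#'
#' @param object A `coalescent_null` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coalescent_null <- function(object, bins = 60, ...) {
  ggplot2::ggplot(object$snps, ggplot2::aes(x = .data$fst)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed",
                        colour = "maroon") +
    ggplot2::labs(
      x = expression("per-SNP" ~ F[ST]),
      y = "loci",
      title = sprintf("two-deme null: mean FST %.3f, %d loci above %.3f",
                      object$mean_fst, object$n_above, object$threshold)
    ) +
    ggplot2::theme_minimal()
}
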