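#' Plot windowed ancestry scores along the chromosome
#'
#' One point per 100-kb (by default) window, with the 75% combined-score
#' expectation for a dominant causal allele drawn as a dashed line and IBD
#' -excluded windows greyed out.
#'
#' @param windows Output of [candidate_windows()].
#' @param target Expected combined score (default 0.75).
#' @return A ggplot object.
#' @export
plot_ancestry_scan <- function(windows, target = 0.75) {
  mid <- (windows$start + windows$end) / 2
  df <- dplyr::mutate(windows, mid = mid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e6, y = .data$combined)) +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$candidate), na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey55"),
                                 name = "candidate") +
    ggplot2::labs(x = "position (Mb)", y = "combined ancestry score") +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window Dxy scan
#'
#' @param scan Output of [sliding_dxy()].
#' @param peaks Optional [peak_interval()] table shaded on the plot.
#' @return A ggplot object.
#' @export
plot_dxy_scan <- function(scan, peaks = NULL) {
  p <- ggplot2::ggplot(scan, ggplot2::aes(x = .data$pos / 1e6,
                                          y = .data$smoothed)) +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::labs(x = "position (Mb)", y = "sliding-window Dxy") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_rect(
      data = peaks,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  p
}

#' Plot a sliding-window HKA scan
#'
#' Plots `-log10(p)` of the windowed polymorphism/divergence test per SNP.
#'
#' @param scan Output of [window_hka()].
#' @return A ggplot object.
#' @export
plot_hka_scan <- function(scan) {
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$pos / 1e6,
                                     y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.5, colour = "darkorange3", na.rm = TRUE) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Plot per-site FST between haplogroups
#'
#' @param fst Output of [per_snp_fst()].
#' @param subregion Optional `c(start, end)` interval highlighted (e.g. the
#'   enhancer annotation of the alignment).
#' @return A ggplot object.
#' @export
plot_fst_sites <- function(fst, subregion = NULL) {
  p <- ggplot2::ggplot(fst, ggplot2::aes(x = .data$pos, y = .data$fst)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0),
                          colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_point(colour = "firebrick", size = 0.8, na.rm = TRUE) +
    ggplot2::labs(x = "alignment position (bp)", y = expression(F[ST])) +
    ggplot2::theme_minimal()
  if (!is.null(subregion)) {
    p <- p + ggplot2::annotate("rect", xmin = subregion[1], xmax = subregion[2],
                               ymin = -Inf, ymax = Inf,
                               fill = "firebrick", alpha = 0.1)
  }
  p
}
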