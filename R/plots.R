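#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Rainfall plot of inter-position distances
#'
#' Scatter of `log10(gap + 1)` along each chromosome; dense target regions
#' show up as low-lying runs of points against the sparse contamination
#' background.
#'
#' @param object a [distance_track()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.distance_track <- function(object, ...) {
  df <- rainfall_export(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$anchor, y = .data$log10_gap)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "log10(gap + 1)",
                  title = "Inter-position distance rainfall") +
    ggplot2::theme_minimal()
}

#' Normalized depth along the genome
#'
#' Windowed normalized depth with the diploid baseline at 1; amplified
#' B-chromosomal regions rise in steps of 0.5 per extra copy.
#'
#' @param object a normalized [depth_track()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.depth_track <- function(object, ...) {
  if (!"norm" %in% names(object)) {
    rlang::abort("normalize_depth() the track before plotting")
  }
  df <- dplyr::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$norm)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "normalized depth (1 = diploid)",
                  title = "Windowed WGS depth") +
    ggplot2::theme_minimal()
}

#' Bar chart of the extra-copy spectrum
#'
#' @param spectrum histogram tibble from [copy_spectrum()].
#' @param n_b optional B count; drawn as a reference line (regions below it
#'   were lost from some Bs, above it amplified within Bs).
#' @return A ggplot.
#' @export
plot_copy_spectrum <- function(spectrum, n_b = NULL) {
  p <- ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$extra_copies,
                                              y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "additional copies", y = "region parts",
                  title = "Copy spectrum of B-chromosomal regions") +
    ggplot2::theme_minimal()
  if (!is.null(n_b)) {
    p <- p + ggplot2::geom_vline(xintercept = n_b, linetype = 2,
                                 colour = "firebrick")
  }
  p
}
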