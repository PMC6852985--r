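#' Plot the insert length distribution
#'
#' Bar chart of clean-read lengths per library; plant small-RNA libraries
#' typically show the 21-nt (miRNA) and 24-nt (het-siRNA) peaks.
#'
#' @param x a [length_profile()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.length_profile <- function(x, ...) {
  d <- as_tibble(x)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Insert length (nt)", y = "Reads") +
    ggplot2::theme_minimal()
  if ("library" %in% names(d)) p <- p + ggplot2::facet_wrap(~library)
  p
}

#' @rdname autoplot.length_profile
#' @export
plot_length_profile <- function(x, ...) autoplot.length_profile(x, ...)

#' Volcano plot of a differential-expression result
#'
#' @param x an `apomir_de` object from [de_test()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.apomir_de <- function(x, ...) {
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                  y = -log10(pmax(.data$padj, 1e-300)),
                                  colour = .data$call)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * attr(x, "fc_threshold"),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(x, "p_threshold")),
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a transcript coverage profile
#'
#' Depth along the transcript with merged loci shaded; useful to see why a
#' transcript was called degradation (tiling across its length) or kept as a
#' novel-miRNA candidate (one narrow locus).
#'
#' @param x a [profile_transcript()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.coverage_profile <- function(x, ...) {
  d <- tibble(position = seq_len(x$length), depth = x$depth)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::labs(
      title = sprintf("%s (breadth %.2f)", x$transcript_id, x$breadth),
      x = "Transcript position (nt)", y = "Depth"
    ) +
    ggplot2::theme_minimal()
  if (nrow(x$loci) > 0) {
    p <- p + ggplot2::geom_rect(
      data = x$loci,
      ggplot2::aes(xmin = .data$start + 1, xmax = .data$end,
                   ymin = 0, ymax = max(d$depth)),
      inherit.aes = FALSE, fill = "tomato", alpha = 0.2
    )
  }
  p
}

#' @rdname autoplot.coverage_profile
#' @export
plot_coverage_profile <- function(x, ...) autoplot.coverage_profile(x, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
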