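category_palette <- c(
  host = "#1b9e77", symbiont = "#d95f02",
  shared = "#7570b3", unassigned = "grey60",
  both = "#7570b3", neither = "grey85"
)

#' Bar chart of a read partition
#'
#' One bar per category showing the percentage of reads; with an
#' `enrichment_result`, bars are faceted (dodged) by round so recruitment
#' across rounds is visible.
#'
#' @param object A `read_partition` or `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.read_partition <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$category, y = .data$percent,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = category_palette) +
    ggplot2::labs(
      x = NULL, y = "% of holobiont reads",
      title = sprintf("Read assignment (k = %d, s = %g%%)",
                      object$params$k, object$params$s_percent)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.read_partition
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = factor(.data$round), y = .data$percent,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = category_palette) +
    ggplot2::labs(x = "Enrichment round", y = "% of holobiont reads",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Per-position origin track of a contig
#'
#' Draws the k-mer origin profile as a coloured track along the contig,
#' with switch points marked — a chimeric fusion shows as adjacent host and
#' symbiont blocks with a switch point near the true breakpoint.
#'
#' @param object An `origin_profile` from [kmer_origin_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.origin_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object$profile,
                       ggplot2::aes(x = .data$position, y = 1,
                                    fill = .data$label)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_fill_manual(values = category_palette, drop = FALSE) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "Contig position (bp)", y = NULL, fill = "Origin") +
    ggplot2::theme_minimal()
  if (length(object$switch_points) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = object$switch_points + 0.5,
                                 linetype = "dashed")
  }
  p
}

#' Scatter of per-read coverage fractions against the two banks
#'
#' Each point is a read placed by its host and symbiont coverage
#' fractions; the similarity threshold splits the plane into the four
#' category quadrants.
#'
#' @param assignments Tibble from [classify_reads()].
#' @param s_percent The threshold to draw, in percent.
#' @return A ggplot.
#' @export
plot_coverage_fractions <- function(assignments, s_percent = 50) {
  thr <- s_percent / 100
  ggplot2::ggplot(assignments,
                  ggplot2::aes(x = .data$fraction_host,
                               y = .data$fraction_symbiont,
                               colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = category_palette) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Fraction covered by host k-mers",
                  y = "Fraction covered by symbiont k-mers",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
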