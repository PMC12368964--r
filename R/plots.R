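# ggplot2 views of the main result types.

#' @export
autoplot.te_density_track <- function(object, breakpoint_regions = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = paste0("TE density (", object$group[1], ")")) +
    ggplot2::theme_minimal()
  if (!is.null(breakpoint_regions)) {
    p <- p + ggplot2::geom_rect(
      data = breakpoint_regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
      inherit.aes = FALSE)
  }
  p
}

#' Dot plot of local match fragments
#'
#' @param fragments `te_match_fragments` tibble from [local_matches()].
#' @return A ggplot: forward matches in grey, reverse matches in orange, the
#'   usual dot-plot reading.
#' @export
plot_dotplot <- function(fragments) {
  ggplot2::ggplot(fragments) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$a_start, xend = .data$a_end,
                   y = ifelse(.data$strand == "+", .data$b_start, .data$b_end),
                   yend = ifelse(.data$strand == "+", .data$b_end,
                                 .data$b_start),
                   colour = .data$strand),
      linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c("+" = "grey40", "-" = "darkorange")) +
    ggplot2::labs(x = "sequence A (bp)", y = "sequence B (bp)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.te_consensus_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(x = "consensus position (bp)", y = "genomic hit depth") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.te_null_grid <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$size / 1000, y = .data$mean_shared,
                               colour = factor(.data$min_length))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "region size (kb)", y = "mean shared families per pair",
                  colour = "min TE length (bp)") +
    ggplot2::theme_minimal()
}

#' Enrichment overview bar plot
#'
#' @param enrichment Rows from [ttest_enrichment()] (several groups bound
#'   together).
#' @param alpha Significance level colouring the bars.
#' @return A ggplot of -log10 p-values by group and chromosome.
#' @export
plot_enrichment <- function(enrichment, alpha = 0.05) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$group, y = -log10(.data$p_value),
                               fill = .data$p_value < alpha &
                                 .data$mean_bp > .data$mean_bg)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~chrom) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60"),
                               name = "enriched") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ italic(P))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
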