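# ggplot2 visualisations of the main result types

#' Plot an AMOVA decomposition
#'
#' Bar chart of the percent of molecular variance at each hierarchical
#' level, annotated with permutation p-values.
#'
#' @param object An `mhc_amova` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mhc_amova <- function(object, ...) {
  tab <- object$table
  tab$level <- factor(tab$level, levels = rev(tab$level))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$level, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("p = %.3f", .data$p)),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of molecular variance",
                  title = "Hierarchical AMOVA") +
    ggplot2::theme_minimal()
}

#' Plot a window selection scan
#'
#' pN - pS along the exon in codon windows, with windows flagged by the
#' two-run permutation rule highlighted.
#'
#' @param object An `mhc_scan` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mhc_scan <- function(object, ...) {
  w <- object$windows
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$stat, fill = .data$flagged)) +
    ggplot2::geom_col(width = (w$end - w$start) * 0.9) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                               name = "flagged") +
    ggplot2::labs(x = "codon position", y = "pN - pS",
                  title = "Window scan for diversifying selection") +
    ggplot2::theme_minimal()
}

#' Stacked allele-frequency bars per site
#'
#' @param counts Allele-count tibble (e.g. [dace_mhc_counts()]).
#' @return A ggplot.
#' @export
plot_allele_frequencies <- function(counts) {
  ac <- allele_columns(counts)
  long <- tidyr::pivot_longer(counts[, c("site_code", ac)], -"site_code",
                              names_to = "allele", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$site_code, y = .data$count,
                                     fill = .data$allele)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "allele frequency") +
    ggplot2::theme_minimal()
}
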