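#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_col
#'   geom_boxplot geom_point scale_fill_gradient2 labs theme_minimal
#'   facet_wrap coord_polar theme element_blank
NULL

#' @export
ggplot2::autoplot

#' Plot a correlation table as an annotated heat map
#'
#' @param object An `rte_correlation` from [correlate_pairs()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rte_correlation <- function(object, ...) {
  d <- as_tibble(object)
  d$stars_lab <- ifelse(d$var1 == d$var2 | d$stars == "ns", "", d$stars)
  ggplot(d, aes(x = .data$var1, y = .data$var2, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = .data$stars_lab), size = 3) +
    scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                         limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot differential-enrichment calls
#'
#' Mean enrichment-score difference (high minus low) per gene set, colored
#' by call.
#'
#' @param object An `rte_differential` from [differential_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rte_differential <- function(object, ...) {
  d <- as_tibble(object)
  d$set_name <- stats::reorder(d$set_name, d$logFC)
  ggplot(d, aes(x = .data$logFC, y = .data$set_name, fill = .data$call)) +
    geom_col() +
    ggplot2::scale_fill_manual(
      values = c(up = "#B2182B", down = "#2166AC", ns = "grey70")) +
    labs(x = "ES difference (high - low)", y = NULL, fill = "call") +
    theme_minimal()
}

#' Plot signature scores across samples
#'
#' @param object An `rte_signature_scores` from [score_signatures()].
#' @param ... Unused.
#' @return A ggplot (one box per signature).
#' @export
autoplot.rte_signature_scores <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$signature, y = .data$score)) +
    geom_boxplot(outlier.size = 0.5) +
    labs(x = NULL, y = "signature score") +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-cell-type contrast results
#'
#' Tile map of -log10 p per (cell type, RTE feature), starred at the usual
#' thresholds.
#'
#' @param object An `rte_celltype_contrast` from [celltype_contrast()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rte_celltype_contrast <- function(object, ...) {
  d <- as_tibble(object)
  d$neglog10p <- -log10(pmax(d$p, 1e-300))
  d$lab <- ifelse(d$stars == "ns", "", d$stars)
  p <- ggplot(d, aes(x = .data$rte_id, y = .data$cell_type,
                     fill = .data$neglog10p)) +
    geom_tile() +
    geom_text(aes(label = .data$lab), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#B2182B") +
    labs(x = NULL, y = NULL, fill = "-log10 p") +
    theme_minimal()
  if ("signature" %in% names(d)) p <- p + facet_wrap(~signature)
  p
}

#' Radar-style up-minus-down pathway summary
#'
#' Polar bar chart of the number of upregulated minus downregulated gene
#' sets per RTE group, faceted by category.
#'
#' @param summary Output of [updown_summary()].
#' @param by Name of the RTE grouping column (default `"rte_id"`).
#' @return A ggplot.
#' @export
plot_updown_radar <- function(summary, by = "rte_id") {
  ggplot(summary, aes(x = .data[[by]], y = .data$up_minus_down,
                      fill = .data$category)) +
    geom_col(position = "dodge") +
    coord_polar() +
    labs(x = NULL, y = "#up - #down") +
    theme_minimal()
}

#' Scatter plot of an RTE score against another per-sample variable
#'
#' @param data A data frame with the two columns.
#' @param x,y Column names (strings).
#' @return A ggplot with a linear trend line.
#' @export
plot_score_scatter <- function(data, x, y) {
  ggplot(data, aes(x = .data[[x]], y = .data[[y]])) +
    geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#B2182B") +
    theme_minimal()
}
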