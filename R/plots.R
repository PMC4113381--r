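#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_tile geom_text
#'   labs scale_fill_gradient2 scale_fill_manual theme_minimal
#' @export
ggplot2::autoplot

#' PCA score scatter plot
#'
#' First two principal components of the samples, colored by zone and
#' shaped by tissue.
#'
#' @param object A `zc_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zc_pca
#' @export
autoplot.zc_pca <- function(object, ...) {
  v <- object$var_explained
  ggplot(object$scores, aes(.data$PC1, .data$PC2,
                            colour = .data$zone, shape = .data$tissue)) +
    geom_point(size = 3) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * v[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * v[2])) +
    theme_minimal()
}

#' Fold-change versus significance plot for a spatial-DE table
#'
#' Log2 fold change (signed toward zone a) against -log10 FDR, with called
#' genes highlighted and the thresholds implied by the calling rule.
#'
#' @param object A `zc_de` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zc_de
#' @export
autoplot.zc_de <- function(object, ...) {
  zp <- attr(object, "zone_pair")
  df <- dplyr::mutate(as_tibble(object),
                      signed_lfc = log2(.data$mean_a / .data$mean_b),
                      neglog_q = -log10(pmax(.data$q_fdr, 1e-300)))
  ggplot(df, aes(.data$signed_lfc, .data$neglog_q, colour = .data$called)) +
    geom_point(alpha = 0.5, size = 0.8) +
    scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                      aesthetics = "colour") +
    labs(x = sprintf("log2 fold change (%s vs %s)", zp[1], zp[2]),
         y = "-log10 FDR", colour = "called") +
    theme_minimal()
}

#' Overlap-family grid
#'
#' Tile grid of the all-pairs directional overlap tests: observed overlap
#' printed over a fill encoding enrichment versus depletion relative to
#' chance.
#'
#' @param object A `zc_overlap_family` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zc_overlap_family
#' @export
autoplot.zc_overlap_family <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      log_ratio = log2(pmax(.data$k, 0.5) / .data$expected),
                      label = sprintf("%d\n(exp %.1f)%s", .data$k, .data$expected,
                                      dplyr::case_when(
                                        .data$direction == "more_than_chance" ~ " *",
                                        .data$direction == "less_than_chance" ~ " v",
                                        .default = "")))
  ggplot(df, aes(.data$list_b, .data$list_a, fill = .data$log_ratio)) +
    geom_tile() +
    geom_text(aes(label = .data$label), size = 3) +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "log2 obs/exp") +
    theme_minimal()
}

#' Z-score heat map of genes by samples
#'
#' @param x An [expr_matrix()].
#' @param genes Gene subset to display (typically DE genes).
#' @param cluster Order samples by [cluster_samples()] (default TRUE).
#' @return A ggplot.
#' @export
plot_zscore_heatmap <- function(x, genes = NULL, cluster = TRUE) {
  z <- suppressWarnings(zscore_matrix(x, genes))
  sample_order <- if (cluster && ncol(z) > 2) {
    cluster_samples(x, genes)$leaf_order
  } else colnames(z)
  df <- as_tibble(as.data.frame(z), rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "z") |>
    dplyr::mutate(sample_id = factor(.data$sample_id, levels = sample_order))
  ggplot(df, aes(.data$sample_id, .data$gene, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "black", high = "red") +
    labs(x = NULL, y = NULL, fill = "z-score") +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
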