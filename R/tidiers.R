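#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy PCA sample scores
#'
#' @param x A `zc_pca` object.
#' @param ... Unused.
#' @return The sample-score tibble (annotations plus `PC1..PCm`).
#' @method tidy zc_pca
#' @export
tidy.zc_pca <- function(x, ...) x$scores

#' One-row PCA summary
#'
#' @param x A `zc_pca` object.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `n_components`, `var_pc1`, `var_pc2`,
#'   `var_pc3`, `var_top3` (explained-variance fractions).
#' @method glance zc_pca
#' @export
glance.zc_pca <- function(x, ...) {
  v <- x$var_explained
  pick <- function(i) if (length(v) >= i) v[i] else NA_real_
  tibble(n_samples = nrow(x$scores), n_components = length(v),
         var_pc1 = pick(1), var_pc2 = pick(2), var_pc3 = pick(3),
         var_top3 = sum(v[seq_len(min(3, length(v)))]))
}

#' Tidy a dendrogram's merge sequence
#'
#' @param x A `zc_dendro` object.
#' @param ... Unused.
#' @return Tibble with one row per merge: `step`, `height`, `left`,
#'   `right` (negative values index leaves, positive values earlier
#'   merges, the [stats::hclust()] convention).
#' @method tidy zc_dendro
#' @export
tidy.zc_dendro <- function(x, ...) {
  tibble(step = seq_along(x$height), height = x$height,
         left = x$merge[, 1], right = x$merge[, 2])
}

#' Tidy median-polish effects
#'
#' @param x A `zc_medpolish` object.
#' @param ... Unused.
#' @return Tibble with `term` ("overall", "row:<id>", "col:<id>") and
#'   `estimate`.
#' @method tidy zc_medpolish
#' @export
tidy.zc_medpolish <- function(x, ...) {
  row_ids <- names(x$row) %||% as.character(seq_along(x$row))
  col_ids <- names(x$col) %||% as.character(seq_along(x$col))
  tibble(term = c("overall", paste0("row:", row_ids), paste0("col:", col_ids)),
         estimate = c(x$overall, unname(x$row), unname(x$col)))
}

#' One-row spatial-DE summary
#'
#' @param x A `zc_de` tibble.
#' @param ... Unused.
#' @return Tibble with the zone pair, thresholds, genes tested, and the
#'   number of calls in each direction.
#' @method glance zc_de
#' @export
glance.zc_de <- function(x, ...) {
  zp <- attr(x, "zone_pair")
  tibble(tissue = attr(x, "tissue"), zone_a = zp[1], zone_b = zp[2],
         fc_threshold = attr(x, "fc_threshold"),
         q_threshold = attr(x, "q_threshold"),
         n_genes = nrow(x),
         n_called = sum(x$called),
         n_up_in_a = sum(x$called & x$direction == "up_in_a"),
         n_up_in_b = sum(x$called & x$direction == "up_in_b"))
}

#' One-row overlap-family summary
#'
#' @param x A `zc_overlap_family` tibble.
#' @param ... Unused.
#' @return Tibble with the number of comparisons, universe size, and counts
#'   of significant overlaps by direction.
#' @method glance zc_overlap_family
#' @export
glance.zc_overlap_family <- function(x, ...) {
  tibble(n_comparisons = nrow(x), N = x$N[1],
         alpha = attr(x, "alpha"),
         family_correct = attr(x, "family_correct"),
         n_more = sum(x$direction == "more_than_chance"),
         n_less = sum(x$direction == "less_than_chance"),
         n_degenerate = sum(x$degenerate))
}
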