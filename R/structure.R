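#' Principal components analysis of samples
#'
#' PCA of samples in gene space: genes are centered (optionally
#' standardized) across samples, samples are projected onto the
#' eigenvectors of their covariance, and per-component explained-variance
#' fractions are reported. Used to check that samples of each zone group
#' together.
#'
#' @param x An [expr_matrix()].
#' @param genes Optional character vector restricting the analysis to a
#'   gene subset (case-insensitive); default all genes.
#' @param mode `"center"` (default, covariance PCA on gene-centered data)
#'   or `"standardize"` (correlation-mode, genes scaled to unit variance;
#'   constant genes dropped).
#' @return Object of class `zc_pca`: list with `scores` (tibble:
#'   `sample_id`, `tissue`, `zone`, `replicate`, `PC1..PCm`),
#'   `var_explained` (fractions summing to 1, non-increasing), and `sdev`.
#' @export
pca_samples <- function(x, genes = NULL, mode = c("center", "standardize")) {
  stopifnot(inherits(x, "expr_matrix"))
  mode <- match.arg(mode)
  vals <- subset_genes(x, genes)
  if (ncol(vals) < 2) abort("PCA needs at least 2 samples.")
  if (mode == "standardize") {
    sds <- apply(vals, 1, sd)
    if (any(sds == 0)) vals <- vals[sds > 0, , drop = FALSE]
    if (nrow(vals) == 0) abort("no non-constant genes to standardize.")
  }
  m <- t(vals)  # samples x genes
  if (sum(apply(m, 2, stats::var)) == 0) abort("zero total variance across samples.")
  fit <- prcomp(m, center = TRUE, scale. = (mode == "standardize"))
  fractions <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x, .name_repair = "minimal")
  names(scores) <- paste0("PC", seq_along(scores))
  scores <- dplyr::bind_cols(x$samples, scores)
  structure(list(scores = scores, var_explained = fractions, sdev = fit$sdev),
            class = "zc_pca")
}

#' @export
print.zc_pca <- function(x, ...) {
  cat(sprintf("<zc_pca> %d samples; top-3 components retain %.1f%% of variance\n",
              nrow(x$scores), 100 * sum(head(x$var_explained, 3))))
  invisible(x)
}

#' Per-gene z-score matrix
#'
#' Standardizes each gene across samples ((x - mean) / sd), the transform
#' behind heat-map visualization. Genes with zero variance become all-zero
#' rows and are flagged.
#'
#' @param x An [expr_matrix()].
#' @param genes Optional gene subset (case-insensitive).
#' @return Numeric matrix of z-scores with attribute `constant_genes`
#'   listing flagged rows; a warning is raised when any exist.
#' @export
zscore_matrix <- function(x, genes = NULL) {
  vals <- subset_genes(x, genes)
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1, sd)
  constant <- rownames(vals)[sdv == 0]
  sdv[sdv == 0] <- 1
  z <- (vals - mu) / sdv
  if (length(constant) > 0) {
    warn(paste0(length(constant), " constant gene(s) z-scored to zero rows."))
  }
  attr(z, "constant_genes") <- constant
  z
}

#' Unsupervised hierarchical clustering of samples
#'
#' Agglomerative clustering of samples using Euclidean distance on per-gene
#' z-scores (by default) and average linkage. Samples are ordered
#' lexicographically by id before clustering so the result is invariant to
#' input column order (deterministic tie-breaking).
#'
#' @param x An [expr_matrix()].
#' @param genes Optional gene subset, typically the genes differentially
#'   expressed between two zones.
#' @param linkage Linkage method passed to [stats::hclust()] (default
#'   `"average"`).
#' @param zscore Standardize genes before computing distances (default
#'   TRUE).
#' @return Object of class `zc_dendro`: list with `hclust` (the fitted
#'   tree), `merge`, `height`, `leaf_order` (sample ids left to right), and
#'   `samples` (the sample sheet).
#' @export
cluster_samples <- function(x, genes = NULL, linkage = "average", zscore = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  vals <- subset_genes(x, genes)
  if (nrow(vals) == 0) abort("empty gene subset.")
  if (ncol(vals) < 2) abort("need at least 2 samples to cluster.")
  if (zscore) {
    mu <- rowMeans(vals); sdv <- apply(vals, 1, sd); sdv[sdv == 0] <- 1
    vals <- (vals - mu) / sdv
  }
  vals <- vals[, order(colnames(vals)), drop = FALSE]
  hc <- hclust(dist(t(vals), method = "euclidean"), method = linkage)
  structure(
    list(hclust = hc, merge = hc$merge, height = hc$height,
         leaf_order = hc$labels[hc$order],
         samples = x$samples[match(hc$labels, x$samples$sample_id), ]),
    class = "zc_dendro"
  )
}

#' @export
print.zc_dendro <- function(x, ...) {
  cat(sprintf("<zc_dendro> %d samples, %d merges (max height %.3g)\n",
              length(x$leaf_order), length(x$height), max(x$height)))
  cat("leaf order:", paste(x$leaf_order, collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.zc_dendro <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

# Restrict the value matrix of an expr_matrix to a case-insensitive gene
# subset, erroring on genes that are absent.
subset_genes <- function(x, genes) {
  vals <- x$values
  if (is.null(genes)) return(vals)
  key <- fold_symbols(rownames(vals))
  want <- unique(fold_symbols(genes))
  missing <- setdiff(want, key)
  if (length(missing) > 0) {
    abort(paste0("gene(s) not in matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  vals[key %in% want, , drop = FALSE]
}
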