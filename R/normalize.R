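#' Quantile normalization
#'
#' Forces every column (array) of a matrix to share the same empirical
#' distribution: each value is replaced by the mean, across columns, of the
#' values holding the same rank. Ties within a column receive the mean of
#' the tied ranks' reference values, so the map is rank-preserving and
#' idempotent.
#'
#' @param m Numeric matrix (probes or genes x samples), any scale.
#' @return A matrix of the same shape; each column's sorted values equal the
#'   per-rank cross-column means.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0) abort("cannot quantile-normalize an empty matrix.")
  if (anyNA(m)) abort("quantile normalization requires complete data.")
  if (ncol(m) == 1) return(m)
  sorted <- apply(m, 2, sort)
  reference <- rowMeans(sorted)
  out <- apply(m, 2, function(col) {
    # mean rank handles ties: tied entries get the mean of the tied
    # reference values
    r <- rank(col, ties.method = "average")
    lo <- floor(r); hi <- ceiling(r)
    (reference[lo] + reference[hi]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Median polish of a two-way table
#'
#' Fits the additive model value = grand + row effect + column effect +
#' residual by alternately sweeping row and column medians (rows first)
#' until the largest absolute change in any effect falls below `tol` or
#' `max_iter` sweeps have run. In probe-set summarization the rows are a
#' gene's probes, the columns are samples, and the per-sample gene summary
#' is grand + column effect.
#'
#' @param block Numeric matrix (one gene's probes x samples).
#' @param tol Convergence tolerance on effect updates.
#' @param max_iter Maximum number of row+column sweeps.
#' @return An object of class `zc_medpolish`: list with `overall`, `row`
#'   (named row effects), `col` (named column effects), `residuals`
#'   (matrix), and `summary` (per-sample summaries, overall + col).
#'   `overall + row[i] + col[j] + residuals[i, j]` reconstructs the input
#'   exactly.
#' @export
median_polish <- function(block, tol = 1e-6, max_iter = 10L) {
  block <- as.matrix(block)
  if (length(block) == 0) abort("cannot median-polish an empty block.")
  r <- numeric(nrow(block))
  ce <- numeric(ncol(block))
  overall <- 0
  z <- block
  for (iter in seq_len(max_iter)) {
    delta <- 0
    rmed <- apply(z, 1, median)
    z <- sweep(z, 1, rmed)
    r <- r + rmed
    shift <- median(ce)
    ce <- ce - shift
    overall <- overall + shift
    delta <- max(delta, max(abs(rmed)), abs(shift))

    cmed <- apply(z, 2, median)
    z <- sweep(z, 2, cmed)
    ce <- ce + cmed
    shift <- median(r)
    r <- r - shift
    overall <- overall + shift
    delta <- max(delta, max(abs(cmed)), abs(shift))
    if (delta < tol) break
  }
  names(r) <- rownames(block)
  names(ce) <- colnames(block)
  dimnames(z) <- dimnames(block)
  structure(
    list(overall = overall, row = r, col = ce, residuals = z,
         summary = overall + ce, iterations = iter),
    class = "zc_medpolish"
  )
}

#' @export
print.zc_medpolish <- function(x, ...) {
  cat(sprintf("<zc_medpolish> overall %.4g, %d row / %d column effects (%d sweeps)\n",
              x$overall, length(x$row), length(x$col), x$iterations))
  invisible(x)
}

#' Elementwise log2 transformation
#'
#' @param m Numeric matrix or vector of linear-scale values.
#' @param offset Constant added before taking logs (default 0).
#' @return `log2(m + offset)`, same shape.
#' @export
log2_transform <- function(m, offset = 0) {
  if (any(m + offset <= 0)) abort("log2_transform requires positive values after the offset.")
  log2(m + offset)
}

#' Summarize a probe-level matrix to one expression value per gene
#'
#' Applies [median_polish()] to each gene's probes x samples block and
#' returns the per-sample summaries (grand + column effect), the
#' median-polish summarization step of RMA.
#'
#' @param values Probe x sample numeric matrix on the log2 scale.
#' @param probe_gene Data frame mapping `probe_id` to `gene`; every row of
#'   `values` must appear exactly once.
#' @param tol,max_iter Passed to [median_polish()].
#' @return Gene x sample numeric matrix, genes in first-appearance order.
#' @export
summarize_probes <- function(values, probe_gene, tol = 1e-6, max_iter = 10L) {
  values <- as.matrix(values)
  probe_gene <- as_tibble(probe_gene)
  if (!all(c("probe_id", "gene") %in% names(probe_gene))) {
    abort("`probe_gene` needs columns 'probe_id' and 'gene'.")
  }
  if (!setequal(probe_gene$probe_id, rownames(values)) ||
      nrow(probe_gene) != nrow(values)) {
    abort("`probe_gene` must map each probe row exactly once.")
  }
  map <- probe_gene$gene[match(rownames(values), probe_gene$probe_id)]
  genes <- unique(map)
  out <- vapply(genes, function(g) {
    median_polish(values[map == g, , drop = FALSE],
                  tol = tol, max_iter = max_iter)$summary
  }, numeric(ncol(values)))
  out <- t(out)
  dimnames(out) <- list(genes, colnames(values))
  out
}
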