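#' Intersect two gene universes
#'
#' Case-insensitive intersection of two symbol sets, the step that restricts
#' cross-platform comparisons to genes measured on both platforms.
#'
#' @param genes_a,genes_b Character vectors of gene symbols.
#' @return Sorted, case-folded (upper-case) shared symbols.
#' @export
intersect_universe <- function(genes_a, genes_b) {
  sort(intersect(unique(fold_symbols(genes_a)), unique(fold_symbols(genes_b))))
}

#' Chi-square test of overlap between two gene lists
#'
#' Tests whether the overlap between two gene lists drawn from a shared
#' universe of N genes is larger or smaller than the chance expectation
#' n_a * n_b / N. Membership in the two lists forms a 2x2 contingency table
#' with cells (k, n_a - k, n_b - k, N - n_a - n_b + k); the statistic is the
#' Pearson chi-square without continuity correction (df = 1), with an
#' upper-tail p-value. Direction (`more_than_chance` / `less_than_chance`)
#' is assigned by the sign of k - expected, but only when the (adjusted)
#' p-value clears `alpha`.
#'
#' @param list_a,list_b Character vectors of gene symbols; restricted to
#'   `universe` (case-insensitively) before counting.
#' @param universe Character vector: the shared gene universe.
#' @param alpha Significance level for direction assignment (default 0.05).
#' @param list_a_id,list_b_id Labels carried into the result.
#' @param p_adj Optional pre-computed adjusted p-value to use for direction
#'   assignment (set by [all_pairs_correspondence()]); defaults to the raw p.
#' @return One-row tibble of class `zc_overlap`: `list_a`, `list_b`, `N`,
#'   `n_a`, `n_b`, `k`, `expected`, `chi2`, `p_raw`, `p_adj`, `direction`,
#'   `degenerate`. Margins of 0 or N make the table degenerate: `p` is NA
#'   and no direction is assigned.
#' @export
directional_overlap_test <- function(list_a, list_b, universe, alpha = 0.05,
                                     list_a_id = "list_a", list_b_id = "list_b",
                                     p_adj = NULL) {
  uni <- unique(fold_symbols(universe))
  N <- length(uni)
  if (N < 1) abort("empty universe.")
  a <- intersect(unique(fold_symbols(list_a)), uni)
  b <- intersect(unique(fold_symbols(list_b)), uni)
  n_a <- length(a); n_b <- length(b)
  k <- length(intersect(a, b))
  expected <- n_a * n_b / N
  degenerate <- n_a %in% c(0L, N) || n_b %in% c(0L, N)
  if (degenerate) {
    chi2 <- NA_real_; p <- NA_real_; padj <- NA_real_; direction <- "none"
  } else {
    o <- c(k, n_a - k, n_b - k, N - n_a - n_b + k)
    e <- c(expected, n_a - expected, n_b - expected, N - n_a - n_b + expected)
    chi2 <- sum((o - e)^2 / e)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    padj <- if (is.null(p_adj)) p else p_adj
    direction <- if (!is.na(padj) && padj < alpha) {
      if (k > expected) "more_than_chance"
      else if (k < expected) "less_than_chance"
      else "none"
    } else "none"
  }
  out <- tibble(
    list_a = list_a_id, list_b = list_b_id,
    N = N, n_a = n_a, n_b = n_b, k = k,
    expected = expected, chi2 = chi2, p_raw = p, p_adj = padj,
    direction = direction, degenerate = degenerate
  )
  class(out) <- c("zc_overlap", class(out))
  out
}

#' Holm-Sidak multiple-comparison adjustment
#'
#' Step-down Sidak adjustment: with the m raw p-values sorted ascending,
#' adjusted p_(i) = 1 - (1 - p_(i))^(m - i + 1), made monotone
#' non-decreasing down the sorted order, capped at 1, and returned in the
#' input order. Uniformly at least as powerful as Bonferroni-Holm under
#' independence.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs passed through).
#' @return Adjusted p-values, same length and order.
#' @export
holm_sidak_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  ord <- ok[order(p[ok])]
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out[ord] <- adj
  out
}

#' All-pairs directional correspondence between two tissues
#'
#' The core cross-tissue inference: every directional gene list of tissue A
#' is tested for overlap against every directional gene list of tissue B
#' over the shared universe, and the whole family of raw chi-square
#' p-values is Holm-Sidak corrected before directions are assigned. With
#' one zone pair in tissue A and three in tissue B (two directions each)
#' this is the 12-comparison design.
#'
#' @param lists_a,lists_b Named lists of character vectors: the directional
#'   gene lists (e.g. from [directional_gene_lists()]) of each tissue.
#' @param universe Shared gene universe (see [intersect_universe()]).
#' @param alpha Significance level for direction assignment.
#' @param family_correct Apply Holm-Sidak across the family (default TRUE);
#'   if FALSE directions use raw p-values.
#' @return Tibble of class `zc_overlap_family`, one row per (list_a,
#'   list_b) combination with the [directional_overlap_test()] columns.
#' @export
all_pairs_correspondence <- function(lists_a, lists_b, universe, alpha = 0.05,
                                     family_correct = TRUE) {
  if (is.null(names(lists_a)) || is.null(names(lists_b))) {
    abort("directional lists must be named.")
  }
  grid <- tidyr::expand_grid(a = names(lists_a), b = names(lists_b))
  raw <- purrr::pmap(grid, function(a, b) {
    directional_overlap_test(lists_a[[a]], lists_b[[b]], universe,
                             alpha = alpha, list_a_id = a, list_b_id = b)
  }) |> purrr::list_rbind()
  padj <- if (family_correct) holm_sidak_adjust(raw$p_raw) else raw$p_raw
  out <- raw |>
    dplyr::mutate(
      p_adj = padj,
      direction = dplyr::case_when(
        .data$degenerate | is.na(.data$p_adj) ~ "none",
        .data$p_adj < alpha & .data$k > .data$expected ~ "more_than_chance",
        .data$p_adj < alpha & .data$k < .data$expected ~ "less_than_chance",
        .default = "none"
      )
    )
  attr(out, "alpha") <- alpha
  attr(out, "family_correct") <- family_correct
  class(out) <- c("zc_overlap_family", setdiff(class(out), "zc_overlap"))
  out
}

#' Localize marker sets within directional gene lists
#'
#' For each zone's marker set, counts how many of its K markers on the
#' shared universe fall in each directional list of a spatial-DE result
#' (k_up of K) and assesses enrichment with the chi-square overlap test.
#' Marker localizations are tested individually (no family correction) by
#' default.
#'
#' @param markers A `zc_marker_sets` tibble (columns `zone`, `gene`) or any
#'   data frame with those columns.
#' @param de A `zc_de` table from [call_spatially_regulated()].
#' @param universe Gene universe the markers and lists are restricted to.
#' @param alpha Significance level for direction assignment.
#' @return Tibble of class `zc_marker_localization`: one row per
#'   (marker set, direction) with `marker_set`, `direction_list`, `K`,
#'   `k_up`, and the overlap-test columns.
#' @export
marker_localization <- function(markers, de, universe, alpha = 0.05) {
  markers <- as_tibble(markers)
  if (!all(c("zone", "gene") %in% names(markers))) {
    abort("`markers` needs columns 'zone' and 'gene'.")
  }
  uni <- unique(fold_symbols(universe))
  lists <- directional_gene_lists(de)
  sets <- split(fold_symbols(markers$gene), markers$zone)
  out <- purrr::imap(sets, function(genes, set_name) {
    on_platform <- intersect(unique(genes), uni)
    if (length(on_platform) == 0) {
      abort(paste0("marker set '", set_name, "' has no genes in the universe."))
    }
    purrr::imap(lists, function(up, list_name) {
      res <- directional_overlap_test(on_platform, up, uni, alpha = alpha,
                                      list_a_id = set_name, list_b_id = list_name)
      tibble(marker_set = set_name, direction_list = list_name,
             K = length(on_platform),
             k_up = res$k) |>
        dplyr::bind_cols(res[c("N", "n_b", "expected", "chi2",
                               "p_raw", "p_adj", "direction", "degenerate")])
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  class(out) <- c("zc_marker_localization", class(out))
  out
}
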