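#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA on k groups: F = MS(between)/MS(within) with
#' (k - 1, N - k) degrees of freedom and an upper-tail p-value. With two
#' groups this is identical to the pooled-variance two-sample t-test
#' (F = t^2).
#'
#' @param groups List of numeric vectors, one per group, each of length >= 2.
#' @return A list with `statistic` (F), `p_value`, `df` (length-2), and
#'   `degenerate` (TRUE when the within-group variance is zero while group
#'   means differ, in which case p is reported as 0 with a warning).
#' @export
one_way_anova_p <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("need at least 2 groups.")
  n <- lengths(groups)
  if (any(n < 2)) abort("every group needs at least 2 values.")
  y <- unlist(groups, use.names = FALSE)
  N <- length(y)
  k <- length(groups)
  m <- vapply(groups, mean, numeric(1))
  grand <- mean(y)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - m[i])^2), numeric(1)))
  df <- c(k - 1, N - k)
  if (ssw <= 0) {
    if (ssb <= 0) {
      return(list(statistic = 0, p_value = 1, df = df, degenerate = FALSE))
    }
    warn("zero residual variance with unequal group means; p reported as 0.")
    return(list(statistic = Inf, p_value = 0, df = df, degenerate = TRUE))
  }
  f <- (ssb / df[1]) / (ssw / df[2])
  list(statistic = f, p_value = pf(f, df[1], df[2], lower.tail = FALSE),
       df = df, degenerate = FALSE)
}

# Vectorized per-row one-way ANOVA for a genes x samples matrix and a group
# factor over columns. Same arithmetic as one_way_anova_p, done with row
# sums so 10^4-gene scans take milliseconds.
row_anova <- function(values, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  n <- as.vector(table(group))
  if (k < 2 || any(n < 2)) abort("need >= 2 groups with >= 2 samples each.")
  N <- ncol(values)
  # group means via an indicator matrix
  ind <- stats::model.matrix(~ group - 1)
  gm <- (values %*% ind) %*% diag(1 / n, nrow = k)
  grand <- rowMeans(values)
  ssb <- rowSums(sweep(gm, 2, n, `*`) * gm) - N * grand^2
  sst <- rowSums(values^2) - N * grand^2
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(f, k - 1, N - k, lower.tail = FALSE)
  # degenerate rows: no residual spread
  zero_w <- ssw <= 1e-12 * pmax(sst, 1e-300)
  p[zero_w & ssb > 1e-12] <- 0
  f[zero_w & ssb > 1e-12] <- Inf
  p[zero_w & ssb <= 1e-12] <- 1
  f[zero_w & ssb <= 1e-12] <- 0
  list(statistic = f, p_value = p, mean_by_group = gm, levels = levels(group))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR q-values: q_(i) = min over j >= i of m * p_(j) / j, capped at
#' 1, returned in the input order. Wraps `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Linear fold change between two group means
#'
#' @param mean_a,mean_b Positive linear-scale group means (antilogged log2
#'   means, i.e. geometric means of the raw signals). Vectorized.
#' @return A tibble with columns `fold_change` (max/min, >= 1), `direction`
#'   (`"up_in_a"`, `"up_in_b"`, or `"none"` on exact equality), and
#'   `fold_change_int` (nearest integer, the convention used in printed
#'   report tables).
#' @examples
#' fold_change(940, 39)  # 24.1, up_in_a, reported as 24
#' @export
fold_change <- function(mean_a, mean_b) {
  if (any(mean_a <= 0) || any(mean_b <= 0)) abort("group means must be positive.")
  fc <- pmax(mean_a, mean_b) / pmin(mean_a, mean_b)
  direction <- dplyr::case_when(
    mean_a > mean_b ~ "up_in_a",
    mean_b > mean_a ~ "up_in_b",
    .default = "none"
  )
  tibble(fold_change = fc, direction = direction,
         fold_change_int = round(fc))
}

#' Call spatially regulated genes between two zones
#'
#' Implements the spatial differential-expression rule: a gene is called
#' spatially regulated between two zones when its expression differs by a
#' fold change of at least `fc_threshold` with a one-way ANOVA
#' Benjamini-Hochberg FDR below `q_threshold`. The ANOVA runs on the log2
#' values of the two zones' samples; group means are antilogged before the
#' fold change so the ratio matches raw-signal arithmetic; BH is applied
#' across all genes tested within this zone pair.
#'
#' @param x An [expr_matrix()] (log2 values).
#' @param zone_a,zone_b Zone labels present in `x$samples$zone`, each with
#'   at least 2 samples.
#' @param fc_threshold Minimum linear fold change (default 2).
#' @param q_threshold FDR ceiling (default 0.05).
#' @return A tibble of class `zc_de`, one row per gene: `gene`, `zone_a`,
#'   `zone_b`, `mean_a`, `mean_b` (linear scale), `fold_change`,
#'   `direction`, `p_raw`, `q_fdr`, `called`. Attributes record the zones,
#'   tissue, thresholds, and platform.
#' @export
call_spatially_regulated <- function(x, zone_a, zone_b,
                                     fc_threshold = 2, q_threshold = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  for (z in c(zone_a, zone_b)) {
    if (sum(x$samples$zone == z) == 0) abort(paste0("unknown zone: ", z))
    if (sum(x$samples$zone == z) < 2) abort(paste0("zone ", z, " has fewer than 2 replicates."))
  }
  sel <- x$samples$zone %in% c(zone_a, zone_b)
  vals <- x$values[, sel, drop = FALSE]
  group <- factor(x$samples$zone[sel], levels = c(zone_a, zone_b))
  fit <- row_anova(vals, group)
  mean_a_log2 <- fit$mean_by_group[, 1]
  mean_b_log2 <- fit$mean_by_group[, 2]
  fc <- fold_change(2^mean_a_log2, 2^mean_b_log2)
  q <- bh_fdr(fit$p_value)
  out <- tibble(
    gene = rownames(vals),
    zone_a = zone_a, zone_b = zone_b,
    mean_a = unname(2^mean_a_log2), mean_b = unname(2^mean_b_log2),
    fold_change = unname(fc$fold_change),
    direction = fc$direction,
    p_raw = unname(fit$p_value),
    q_fdr = unname(q),
    called = unname(fc$fold_change >= fc_threshold & q < q_threshold &
      fc$direction != "none")
  )
  tissue <- unique(x$samples$tissue[sel])
  attr(out, "zone_pair") <- c(zone_a, zone_b)
  attr(out, "tissue") <- if (length(tissue) == 1) tissue else NA_character_
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "q_threshold") <- q_threshold
  attr(out, "platform") <- x$platform
  class(out) <- c("zc_de", class(out))
  out
}

#' Directional gene lists from a spatial-DE table
#'
#' Splits the called genes of a `zc_de` table into the two disjoint
#' directional lists (genes up on each side of the zone pair).
#'
#' @param de A `zc_de` tibble from [call_spatially_regulated()].
#' @return A named list of two character vectors; names are
#'   `"<zone_a>><zone_b>"` (up in a) and `"<zone_b>><zone_a>"` (up in b).
#' @export
directional_gene_lists <- function(de) {
  stopifnot(inherits(de, "zc_de"))
  zp <- attr(de, "zone_pair")
  up_a <- de$gene[de$called & de$direction == "up_in_a"]
  up_b <- de$gene[de$called & de$direction == "up_in_b"]
  setNames(list(up_a, up_b),
           c(paste0(zp[1], ">", zp[2]), paste0(zp[2], ">", zp[1])))
}
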