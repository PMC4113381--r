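# Independent oracles and small fixture builders shared across tests.

# Brute-force Pearson chi-square over the 2x2 membership table.
chi2_oracle <- function(N, n_a, n_b, k) {
  o <- c(k, n_a - k, n_b - k, N - n_a - n_b + k)
  e_k <- n_a * n_b / N
  e <- c(e_k, n_a - e_k, n_b - e_k, N - n_a - n_b + e_k)
  sum((o - e)^2 / e)
}

# Build gene lists realizing the 2x2 configuration (N, n_a, n_b, k).
lists_for_counts <- function(N, n_a, n_b, k) {
  uni <- sprintf("G%05d", seq_len(N))
  a <- uni[seq_len(n_a)]
  b <- c(uni[seq_len(k)], uni[n_a + seq_len(n_b - k)])
  list(a = a, b = b, universe = uni)
}

# Iterative row/column median-sweep oracle for median polish (independent
# of the package implementation; mirrors the textbook algorithm).
medpolish_oracle <- function(x, iter = 50) {
  r <- numeric(nrow(x)); ce <- numeric(ncol(x)); overall <- 0
  z <- x
  for (i in seq_len(iter)) {
    rm_ <- apply(z, 1, median); z <- sweep(z, 1, rm_); r <- r + rm_
    s <- median(ce); ce <- ce - s; overall <- overall + s
    cm <- apply(z, 2, median); z <- sweep(z, 2, cm); ce <- ce + cm
    s <- median(r); r <- r - s; overall <- overall + s
  }
  list(overall = overall, row = r, col = ce, residuals = z)
}

# Small two-zone expression fixture with explicit per-gene values.
toy_expr <- function(values, zones, tissue = "toy", platform = "toy") {
  samples <- tibble::tibble(
    sample_id = colnames(values),
    tissue = tissue,
    zone = zones,
    replicate = as.character(stats::ave(seq_along(zones), zones, FUN = seq_along))
  )
  expr_matrix(values, samples, platform = platform)
}

# Directional lists for every zone pair of a tissue's expression matrix.
all_directional_lists <- function(expr, fc_threshold = 2, q_threshold = 0.05) {
  zones <- unique(expr$samples$zone)
  pairs <- utils::combn(zones, 2, simplify = FALSE)
  out <- list()
  for (zp in pairs) {
    de <- call_spatially_regulated(expr, zp[1], zp[2],
                                   fc_threshold = fc_threshold,
                                   q_threshold = q_threshold)
    out <- c(out, directional_gene_lists(de))
  }
  out
}

# Planted truth restricted to one (tissue, zone pair, direction).
truth_genes <- function(truth, tissue, zone_a, zone_b, direction) {
  p <- truth$planted
  p$gene[p$tissue == tissue & p$zone_a == zone_a &
           p$zone_b == zone_b & p$direction == direction]
}
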