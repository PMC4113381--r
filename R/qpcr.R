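#' Read a qPCR CT table
#'
#' CSV with columns `animal`, `zone`, `gene`, `replicate`, `ct` (threshold
#' cycles, one row per reaction well).
#'
#' @param path Path to the CSV.
#' @return A tibble with those five columns; `ct` numeric and positive.
#' @export
read_qpcr <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("animal", "zone", "gene", "replicate", "ct")
  if (!all(needed %in% names(tab))) {
    abort(paste0("qPCR table needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(tab$ct <= 0)) abort("CT values must be positive.")
  tab[needed]
}

#' Collapse technical replicates to mean CT
#'
#' Averages the technical (well) replicates of each (animal, zone, gene)
#' condition at the CT level, the standard practice before biological
#' statistics.
#'
#' @param table qPCR tibble with columns `animal`, `zone`, `gene`,
#'   `replicate`, `ct`.
#' @return Tibble with one row per (animal, zone, gene): `ct` (mean) and
#'   `n_reps`.
#' @export
collapse_replicates <- function(table) {
  table <- as_tibble(table)
  table |>
    dplyr::group_by(.data$animal, .data$zone, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), n_reps = dplyr::n(), .groups = "drop")
}

#' Delta-delta-CT relative expression
#'
#' Relative expression of a gene versus the reference (housekeeping) gene:
#' `2^-(ct_gene - ct_ref) * 1e6`. The 10^6 factor scales values into a
#' convenient range and cancels in all zone comparisons.
#'
#' @param ct_gene,ct_ref Threshold cycles (vectorized).
#' @return Relative expression on the x10^6 scale.
#' @examples
#' relative_expression(20, 20)   # 1e6
#' relative_expression(22, 12)   # 2^-10 * 1e6 = 976.5625
#' @export
relative_expression <- function(ct_gene, ct_ref) {
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_ref))) {
    abort("CT values must be finite.")
  }
  2^-(ct_gene - ct_ref) * 1e6
}

#' Per-condition relative expression from a CT table
#'
#' Collapses technical replicates to mean CT, then normalizes every gene to
#' the reference gene measured in the same (animal, zone) via
#' [relative_expression()].
#'
#' @param table qPCR CT tibble (see [read_qpcr()]).
#' @param reference_gene Housekeeping gene symbol (default `"Rn18s"`, 18S
#'   ribosomal RNA).
#' @return Tibble with one row per (animal, zone, non-reference gene):
#'   columns `animal`, `zone`, `gene`, `ct`, `ct_ref`, `rel_expr`,
#'   `log2_rel_expr`.
#' @export
relative_expression_table <- function(table, reference_gene = "Rn18s") {
  ct <- collapse_replicates(table)
  is_ref <- fold_symbols(ct$gene) == fold_symbols(reference_gene)
  if (!any(is_ref)) abort(paste0("reference gene '", reference_gene, "' not in table."))
  ref <- ct[is_ref, c("animal", "zone", "ct")]
  names(ref)[3] <- "ct_ref"
  missing_ref <- dplyr::anti_join(dplyr::distinct(ct[c("animal", "zone")]),
                                  ref[c("animal", "zone")],
                                  by = c("animal", "zone"))
  if (nrow(missing_ref) > 0) {
    abort(paste0("reference gene missing for animal/zone: ",
                 paste(paste(missing_ref$animal, missing_ref$zone, sep = "/"),
                       collapse = ", ")))
  }
  ct[!is_ref, ] |>
    dplyr::inner_join(ref, by = c("animal", "zone")) |>
    dplyr::mutate(rel_expr = relative_expression(.data$ct, .data$ct_ref),
                  log2_rel_expr = log2(.data$rel_expr)) |>
    dplyr::select("animal", "zone", "gene", "ct", "ct_ref",
                  "rel_expr", "log2_rel_expr")
}

# One-way repeated-measures ANOVA, one observation per (subject, level):
# the level effect is tested against the subject x level residual after
# removing the subject effect.
rm_anova <- function(y, subject, level) {
  subject <- factor(subject); level <- factor(level)
  n <- nlevels(subject); k <- nlevels(level)
  if (n < 2) abort("repeated-measures ANOVA needs >= 2 subjects.")
  tab <- table(subject, level)
  if (any(tab != 1)) {
    miss <- which(tab != 1, arr.ind = TRUE)
    abort(paste0("unbalanced design; cells not singly observed: ",
                 paste(paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
                             sep = "/"), collapse = ", ")))
  }
  grand <- mean(y)
  mz <- tapply(y, level, mean)
  ms <- tapply(y, subject, mean)
  ss_level <- n * sum((mz - grand)^2)
  ss_subj <- k * sum((ms - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- max(ss_tot - ss_level - ss_subj, 0)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  if (ss_res <= 0) {
    if (ss_level <= 0) return(list(statistic = 0, p_value = 1, df = c(df1, df2)))
    return(list(statistic = Inf, p_value = 0, df = c(df1, df2)))
  }
  f <- (ss_level / df1) / (ss_res / df2)
  list(statistic = f, p_value = pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

#' Zone-comparison statistics for qPCR relative expression
#'
#' For each gene, runs a one-way repeated-measures ANOVA on log2 relative
#' expression across zones (within-subject factor: zone; subjects:
#' animals), followed by two-sided paired t-tests for the predetermined
#' zone comparisons. Requires every animal measured in every compared zone.
#'
#' @param rel Tibble from [relative_expression_table()] (columns `animal`,
#'   `zone`, `gene`, `log2_rel_expr`).
#' @param comparisons List of length-2 character vectors of zone labels,
#'   e.g. `list(c("SZ","IDZ"), c("RZ","PZ"), c("PZ","HZ"), c("RZ","HZ"))`.
#' @param alpha Two-tailed significance threshold (default 0.05).
#' @return Tibble of class `zc_qpcr_stats`, one row per (gene, comparison):
#'   `gene`, `anova_F`, `anova_p` (per gene, repeated across its rows),
#'   `zone_a`, `zone_b`, `mean_log2_diff`, `t`, `df`, `p_paired`,
#'   `significant`.
#' @export
zone_statistics <- function(rel, comparisons, alpha = 0.05) {
  rel <- as_tibble(rel)
  if (!all(c("animal", "zone", "gene", "log2_rel_expr") %in% names(rel))) {
    abort("`rel` must come from relative_expression_table().")
  }
  out <- rel |>
    dplyr::group_split(.data$gene) |>
    purrr::map(function(g) {
      gene <- g$gene[1]
      an <- rm_anova(g$log2_rel_expr, g$animal, g$zone)
      purrr::map(comparisons, function(pair) {
        a <- g[g$zone == pair[1], ]
        b <- g[g$zone == pair[2], ]
        a <- a[order(a$animal), ]; b <- b[order(b$animal), ]
        if (!identical(a$animal, b$animal) || nrow(a) < 2) {
          abort(paste0("gene ", gene, ": zones ", pair[1], "/", pair[2],
                       " not measured in the same >= 2 animals."))
        }
        d <- a$log2_rel_expr - b$log2_rel_expr
        if (sd(d) == 0) {
          tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                     parameter = length(d) - 1,
                     p.value = if (mean(d) == 0) 1 else 0)
        } else {
          tt <- t.test(d)
        }
        tibble(gene = gene, anova_F = an$statistic, anova_p = an$p_value,
               zone_a = pair[1], zone_b = pair[2],
               mean_log2_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_paired = tt$p.value,
               significant = tt$p.value < alpha)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  class(out) <- c("zc_qpcr_stats", class(out))
  out
}
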