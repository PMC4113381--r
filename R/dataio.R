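#' Construct an annotated expression matrix
#'
#' Bundles a genes x samples matrix of log2 expression values with a sample
#' sheet assigning each column to a tissue, zone, and replicate, plus a
#' platform label. This is the container every analysis stage consumes.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). Values are log2 intensities.
#' @param samples Data frame with columns `sample_id`, `tissue`, `zone`,
#'   `replicate`; one row per column of `values`, in any order.
#' @param platform Label for the measurement platform (used when
#'   intersecting gene universes across datasets).
#'
#' @details Gene symbols must be unique after case-folding ("Prg4" and
#'   "PRG4" are the same gene). Use [collapse_duplicate_genes()] first if
#'   your matrix carries one row per probe set.
#'
#' @return An object of class `expr_matrix`.
#' @seealso [read_expression()], [as_tibble.expr_matrix()]
#' @export
expr_matrix <- function(values, samples, platform = "platform_1") {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("`values` must be a numeric matrix.")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs gene rownames and sample colnames.")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("expression values must all be finite (no NA/NaN/Inf).")
  }
  if (anyDuplicated(fold_symbols(rownames(values)))) {
    abort("gene symbols must be unique after case-folding; see collapse_duplicate_genes().")
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "tissue", "zone", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples[required] <- lapply(samples[required], as.character)
  if (anyDuplicated(samples$sample_id)) abort("sample ids must be unique.")
  unmatched <- setdiff(colnames(values), samples$sample_id)
  if (length(unmatched) > 0) {
    abort(paste0("no sample metadata for: ", paste(unmatched, collapse = ", ")))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  structure(
    list(values = values, samples = samples, platform = as.character(platform)),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, platform '%s'\n",
              nrow(x$values), ncol(x$values), x$platform))
  zones <- table(x$samples$tissue, x$samples$zone)
  print(zones)
  invisible(x)
}

#' Long (tidy) view of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample_id`, `tissue`, `zone`,
#'   `replicate`, `value` (log2 expression).
#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  long <- tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample_id") |>
    dplyr::select("gene", "sample_id", "tissue", "zone", "replicate", "value")
}

#' Collapse duplicate gene symbols to one row per gene
#'
#' Probe-set arrays yield several rows per gene. Rows sharing a case-folded
#' symbol are collapsed to a single representative: the row with the
#' smallest p-value when a per-row p-value is supplied (a spatial-DE
#' context), otherwise the row with the highest mean expression.
#'
#' @param values Numeric matrix with gene-symbol rownames.
#' @param p Optional numeric vector of per-row p-values (same length as
#'   `nrow(values)`) used to pick the representative row.
#' @return The matrix restricted to one row per case-folded symbol, in
#'   first-appearance order.
#' @export
collapse_duplicate_genes <- function(values, p = NULL) {
  values <- as.matrix(values)
  key <- fold_symbols(rownames(values))
  if (!is.null(p) && length(p) != nrow(values)) {
    abort("`p` must have one value per row of `values`.")
  }
  score <- if (is.null(p)) -rowMeans(values) else p
  keep <- tibble(idx = seq_len(nrow(values)), key = key, score = score) |>
    dplyr::group_by(.data$key) |>
    dplyr::slice_min(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$idx) |>
    dplyr::pull(.data$idx)
  values[keep, , drop = FALSE]
}

#' Read an expression matrix and its sample sheet
#'
#' The expression file is tab-separated with a first column `gene` and one
#' column per sample id; lines starting with `#` are ignored. The sample
#' sheet (CSV or TSV, sniffed from the extension) must carry columns
#' `sample_id`, `tissue`, `zone`, `replicate` covering every matrix column.
#'
#' @param matrix_path Path to the TSV expression matrix (log2 values).
#' @param sample_sheet_path Path to the sample sheet.
#' @param platform Platform label to attach.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(matrix_path, sample_sheet_path, platform = "platform_1") {
  raw <- readr::read_tsv(matrix_path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (names(raw)[1] != "gene") abort("expression matrix must have a first column named 'gene'.")
  num <- raw[-1]
  bad <- which(!vapply(num, is.numeric, logical(1)))
  if (length(bad) > 0) {
    # locate the first offending cell for the error message
    col <- names(num)[bad[1]]
    row <- which(is.na(suppressWarnings(as.numeric(num[[bad[1]]]))))[1]
    abort(sprintf("non-numeric expression value at gene row %d, sample column '%s'.",
                  row, col))
  }
  values <- as.matrix(num)
  rownames(values) <- raw$gene
  values <- collapse_duplicate_genes(values)
  sheet <- if (grepl("\\.csv$", sample_sheet_path, ignore.case = TRUE)) {
    readr::read_csv(sample_sheet_path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(sample_sheet_path, show_col_types = FALSE, progress = FALSE)
  }
  expr_matrix(values, sheet, platform = platform)
}

#' Write an expression matrix and sample sheet to disk
#'
#' Inverse of [read_expression()]: values go to a TSV with a `gene` first
#' column, metadata to a TSV sample sheet.
#'
#' @param x An `expr_matrix`.
#' @param matrix_path,sample_sheet_path Output paths.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, matrix_path, sample_sheet_path) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- as_tibble(as.data.frame(x$values), rownames = "gene")
  write_table(tab, matrix_path)
  write_table(x$samples, sample_sheet_path)
  invisible(x)
}

#' Read zone marker sets
#'
#' Reads a two-column (zone, gene) TSV of known zonal marker genes, e.g.
#' resting/proliferative/hypertrophic-zone markers. Genes are case-folded
#' and de-duplicated within each zone; zone labels are kept verbatim.
#'
#' @param path Path to the marker TSV (columns `zone`, `gene`; `#` comments
#'   allowed).
#' @return A tibble of class `zc_marker_sets` with columns `zone`, `gene`,
#'   one row per unique (zone, gene).
#' @export
read_marker_sets <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("zone", "gene") %in% names(tab))) {
    abort("marker file needs columns 'zone' and 'gene'.")
  }
  if (nrow(tab) == 0) abort("marker file is empty.")
  out <- tab |>
    dplyr::transmute(zone = as.character(.data$zone),
                     gene = fold_symbols(.data$gene)) |>
    dplyr::distinct()
  class(out) <- c("zc_marker_sets", class(out))
  out
}

#' Write a result table as TSV
#'
#' Writes any data frame of results with a header row, floats rendered with
#' 6 significant digits, `NA`/`NaN` serialized as "NA", and rows in their
#' given (deterministic) order.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_table <- function(records, path) {
  records <- as.data.frame(records)
  fmt <- lapply(records, function(col) {
    if (is.double(col)) {
      out <- formatC(col, digits = 6, format = "g")
      out[!is.finite(col) & !is.na(col)] <- as.character(col[!is.finite(col) & !is.na(col)])
      out[is.na(col)] <- NA_character_
      out
    } else if (is.logical(col) || is.numeric(col)) {
      as.character(col)
    } else {
      as.character(col)
    }
  })
  out <- as.data.frame(fmt, optional = TRUE)
  names(out) <- names(records)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(records)
}

#' Read a result table written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble with column types guessed by readr.
#' @export
read_result_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
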