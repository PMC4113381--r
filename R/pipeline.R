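#' Read a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration for [run_pipeline()], filling in
#' the default thresholds: fold-change 2, FDR 0.05, overlap alpha 0.05,
#' family correction on.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A named list with defaults applied.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  apply_config_defaults(cfg)
}

apply_config_defaults <- function(cfg) {
  defaults <- list(fc_threshold = 2, q_threshold = 0.05, alpha = 0.05,
                   family_correction = TRUE, linkage = "average",
                   pca_mode = "center", seed = 1L)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  cfg
}

validate_config <- function(cfg) {
  if (cfg$fc_threshold <= 0 || cfg$q_threshold <= 0 || cfg$alpha <= 0) {
    abort("thresholds must be positive.", class = "zc_config_error")
  }
  if (!is.null(cfg$simulation)) {
    if (!inherits(cfg$simulation, "simulation_design")) {
      abort("`simulation` must be a simulation_design object.",
            class = "zc_config_error")
    }
    for (zones in cfg$simulation$tissues) {
      if (anyDuplicated(zones)) {
        abort("zones must be unique within a tissue.", class = "zc_config_error")
      }
    }
  } else {
    need <- c("expression_a", "samples_a", "expression_b", "samples_b")
    if (!all(need %in% names(cfg))) {
      abort("config needs either `simulation` or the four input paths.",
            class = "zc_config_error")
    }
  }
  invisible(cfg)
}

#' Run the end-to-end zonal correspondence pipeline
#'
#' Orchestrates every stage on a pair of zonal datasets (simulated from a
#' design, or read from disk): per-tissue spatial-DE calling for every zone
#' pair, cross-platform universe intersection, the all-pairs directional
#' overlap family with Holm-Sidak correction, optional marker-set
#' localization, sample-structure analyses (PCA, clustering, z-scores), and
#' optional qPCR zone statistics. All tables are written to `outdir`
#' together with a JSON run manifest (parameters, seed, versions) and a log
#' with one line per stage.
#'
#' @param config Named list (see [read_pipeline_config()]) with either
#'   `simulation` (a [simulation_design()]) or input paths
#'   `expression_a`/`samples_a`/`expression_b`/`samples_b`; optional
#'   `markers` (path or marker tibble), `qpcr` (path or CT tibble),
#'   `qpcr_reference` and `qpcr_comparisons`; thresholds `fc_threshold`,
#'   `q_threshold`, `alpha`; `family_correction`; structure options
#'   `linkage`, `pca_mode`; `seed`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with every in-memory result (`de`, `lists`,
#'   `universe`, `overlaps`, `markers`, `pca`, `dendro`, `qpcr`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  cfg <- validate_config(apply_config_defaults(config))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    writeLines(line, log_con)
    message(line)
  }
  fail_marker <- file.path(outdir, "FAILED")
  ok <- FALSE
  on.exit({
    if (!ok) writeLines("pipeline aborted; partial outputs retained.", fail_marker)
  }, add = TRUE)

  # ---- inputs ----
  if (!is.null(cfg$simulation)) {
    stage("simulate: generating tissue pair from design")
    sim <- simulate_tissue_pair(cfg$simulation)
    exprs <- list(sim$expr_a, sim$expr_b)
    truth <- sim$truth
  } else {
    stage("load: reading expression matrices")
    exprs <- list(
      read_expression(cfg$expression_a, cfg$samples_a, platform = "platform_a"),
      read_expression(cfg$expression_b, cfg$samples_b, platform = "platform_b")
    )
    truth <- NULL
  }
  tissues <- vapply(exprs, function(e) e$samples$tissue[1], "")
  names(exprs) <- tissues

  # ---- spatial DE per tissue, per zone pair ----
  de <- list(); lists <- list()
  for (t in tissues) {
    zones <- unique(exprs[[t]]$samples$zone)
    pairs <- utils::combn(zones, 2, simplify = FALSE)
    for (zp in pairs) {
      key <- paste0(t, ":", zp[1], "-", zp[2])
      stage(paste0("spatial_de: ", key))
      d <- call_spatially_regulated(exprs[[t]], zp[1], zp[2],
                                    fc_threshold = cfg$fc_threshold,
                                    q_threshold = cfg$q_threshold)
      de[[key]] <- d
      dl <- directional_gene_lists(d)
      lists[[t]] <- c(lists[[t]], dl)
      write_table(d, file.path(outdir, paste0("de_", gsub(":", "_", key), ".tsv")))
      dl_tab <- purrr::imap(dl, function(g, nm) tibble(gene = g, direction = nm)) |>
        purrr::list_rbind()
      write_table(dl_tab, file.path(outdir, paste0("lists_", gsub(":", "_", key), ".tsv")))
    }
  }

  # ---- cross-platform correspondence ----
  stage("correspond: universe intersection and overlap family")
  universe <- intersect_universe(rownames(exprs[[1]]$values),
                                 rownames(exprs[[2]]$values))
  writeLines(universe, file.path(outdir, "universe.txt"))
  overlaps <- all_pairs_correspondence(lists[[tissues[1]]], lists[[tissues[2]]],
                                       universe, alpha = cfg$alpha,
                                       family_correct = isTRUE(cfg$family_correction))
  write_table(overlaps, file.path(outdir, "overlap_results.tsv"))

  # ---- marker localization ----
  marker_res <- NULL
  if (!is.null(cfg[["markers"]])) {
    stage("markers: zonal marker localization")
    markers <- if (is.character(cfg[["markers"]])) read_marker_sets(cfg[["markers"]]) else
      as_tibble(cfg[["markers"]])
    marker_res <- marker_localization(markers, de[[1]], universe,
                                      alpha = cfg$alpha)
    write_table(marker_res, file.path(outdir, "marker_localization.tsv"))
  } else {
    stage("markers: skipped (no marker list supplied)")
  }

  # ---- sample structure on the first tissue ----
  stage("structure: PCA, clustering, z-scores")
  pca <- pca_samples(exprs[[1]], mode = cfg$pca_mode)
  write_table(pca$scores, file.path(outdir, "pca_scores.tsv"))
  write_table(tibble(component = seq_along(pca$var_explained),
                     fraction = pca$var_explained),
              file.path(outdir, "pca_variance.tsv"))
  de_genes <- de[[1]]$gene[de[[1]]$called]
  dendro <- NULL
  if (length(de_genes) >= 2) {
    dendro <- cluster_samples(exprs[[1]], genes = de_genes,
                              linkage = cfg$linkage)
    jsonlite::write_json(dendro_to_list(dendro),
                         file.path(outdir, "dendrogram.json"),
                         auto_unbox = TRUE, digits = NA)
    z <- suppressWarnings(zscore_matrix(exprs[[1]], genes = de_genes))
    write_table(as_tibble(as.data.frame(z), rownames = "gene"),
                file.path(outdir, "zscores.tsv"))
  }

  # ---- qPCR ----
  qpcr_res <- NULL
  if (!is.null(cfg[["qpcr"]])) {
    stage("qpcr: delta-delta-CT zone statistics")
    ctab <- if (is.character(cfg[["qpcr"]])) read_qpcr(cfg[["qpcr"]]) else
      as_tibble(cfg[["qpcr"]])
    rel <- relative_expression_table(
      ctab, reference_gene = cfg[["qpcr_reference"]] %||% "Rn18s")
    comps <- cfg[["qpcr_comparisons"]] %||%
      list(c("SZ", "IDZ"), c("RZ", "PZ"), c("PZ", "HZ"), c("RZ", "HZ"))
    qpcr_res <- zone_statistics(rel, comps, alpha = cfg$alpha)
    write_table(rel, file.path(outdir, "qpcr_relative_expression.tsv"))
    write_table(qpcr_res, file.path(outdir, "qpcr_statistics.tsv"))
  } else {
    stage("qpcr: skipped (no CT data supplied)")
  }

  # ---- manifest ----
  stage("manifest: writing run manifest")
  manifest <- list(
    package = "zonecor",
    version = as.character(utils::packageVersion("zonecor")),
    seed = cfg$seed,
    parameters = list(fc_threshold = cfg$fc_threshold,
                      q_threshold = cfg$q_threshold,
                      alpha = cfg$alpha,
                      family_correction = isTRUE(cfg$family_correction),
                      linkage = cfg$linkage, pca_mode = cfg$pca_mode),
    tissues = as.list(setNames(lapply(exprs, function(e) unique(e$samples$zone)),
                               tissues)),
    universe_size = length(universe),
    n_overlap_tests = nrow(overlaps),
    stages_skipped = c(if (is.null(cfg[["markers"]])) "markers",
                       if (is.null(cfg[["qpcr"]])) "qpcr")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  ok <- TRUE
  invisible(list(expr = exprs, truth = truth, de = de, lists = lists,
                 universe = universe, overlaps = overlaps,
                 markers = marker_res, pca = pca, dendro = dendro,
                 qpcr = qpcr_res, manifest = manifest))
}

# Nested-list form of a dendrogram for JSON serialization.
dendro_to_list <- function(x) {
  hc <- x$hclust
  build <- function(i) {
    if (i < 0) return(list(leaf = hc$labels[-i]))
    list(height = hc$height[i],
         left = build(hc$merge[i, 1]),
         right = build(hc$merge[i, 2]))
  }
  build(nrow(hc$merge))
}
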