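#' Define a zonal expression program
#'
#' A program is a set of genes sharing a zone-specific log2 expression
#' effect, the generative counterpart of a block of spatially upregulated
#' genes. Genes may be fixed up front or left NULL to be assigned from the
#' platform universe at simulation time.
#'
#' @param name Program label.
#' @param effects Named numeric vector: zone label -> log2 effect added to
#'   the baseline for genes of this program in that zone (finite values).
#' @param size Number of genes to assign when `genes` is NULL.
#' @param genes Optional fixed character vector of gene symbols.
#' @return Object of class `zone_program`.
#' @export
zone_program <- function(name, effects, size = NULL, genes = NULL) {
  if (is.null(names(effects)) || any(!is.finite(effects))) {
    abort("`effects` must be a named, finite numeric vector (zone -> log2 effect).")
  }
  if (is.null(genes) && (is.null(size) || size < 1)) {
    abort("give either `genes` or a positive `size`.")
  }
  if (!is.null(genes) && length(genes) == 0) abort("gene set must be non-empty.")
  structure(list(name = name, effects = effects,
                 size = if (is.null(genes)) as.integer(size) else length(genes),
                 genes = genes),
            class = "zone_program")
}

#' Specify a zonal tissue-pair simulation
#'
#' Describes one or two spatially stratified tissues measured on (possibly
#' different) platforms: ordered zones, replicate counts, baseline and
#' noise levels on the log2 scale, planted zone programs, and the sharing
#' structure linking programs across tissues.
#'
#' @param tissues Named list: tissue label -> ordered character vector of
#'   zone labels.
#' @param n_genes Genes per platform.
#' @param n_replicates Replicate samples per zone (default 4, the study
#'   design).
#' @param baseline_range Length-2 range for per-gene baseline log2 means
#'   (default c(5, 12), a typical array intensity range).
#' @param sigma Gaussian replicate noise sd in log2 units (default 0.35).
#' @param programs Named list: tissue label -> list of [zone_program()]s.
#' @param shared_links List of length-2 character vectors
#'   `c("tissueA:programName", "tissueB:programName")` designating program
#'   pairs that share genes across tissues.
#' @param shared_fraction rho in \[0, 1\]: fraction of each linked
#'   program's genes drawn from the cross-platform intersection and planted
#'   in both tissues (default 0.8).
#' @param platform_overlap Fraction of each platform's genes present on
#'   both platforms, in \[0, 1\] (default 0.9).
#' @param effect_spread Per-gene effect magnitudes are the program's base
#'   effect times Uniform(1, `effect_spread`) (default 2.5), mimicking the
#'   wide range of fold changes real zonal programs show. Set to 1 for
#'   identical effects.
#' @param truth_fc_threshold Fold-change threshold defining which planted
#'   genes the truth records as spatially regulated for a zone pair
#'   (default 2: planted |log2 effect difference| >= 1).
#' @param seed Integer master seed; all per-stage streams derive from it.
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(tissues, n_genes = 2000, n_replicates = 4,
                              baseline_range = c(5, 12), sigma = 0.35,
                              programs = list(), shared_links = list(),
                              shared_fraction = 0.8, platform_overlap = 0.9,
                              effect_spread = 2.5, truth_fc_threshold = 2,
                              seed = 1L) {
  if (is.null(names(tissues)) || any(names(tissues) == "")) {
    abort("`tissues` must be a named list of zone vectors.")
  }
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (n_replicates < 2) abort("`n_replicates` must be >= 2.")
  if (n_genes < 1) abort("`n_genes` must be positive.")
  if (shared_fraction < 0 || shared_fraction > 1) abort("`shared_fraction` must lie in [0, 1].")
  if (platform_overlap < 0 || platform_overlap > 1) abort("`platform_overlap` must lie in [0, 1].")
  if (effect_spread < 1) abort("`effect_spread` must be >= 1.")
  for (tis in names(programs)) {
    if (!tis %in% names(tissues)) abort(paste0("programs given for unknown tissue: ", tis))
    for (pr in programs[[tis]]) {
      stopifnot(inherits(pr, "zone_program"))
      unknown <- setdiff(names(pr$effects), tissues[[tis]])
      if (length(unknown) > 0) {
        abort(paste0("program '", pr$name, "' names zone(s) not in tissue ",
                     tis, ": ", paste(unknown, collapse = ", ")))
      }
    }
  }
  structure(
    list(tissues = tissues, n_genes = as.integer(n_genes),
         n_replicates = as.integer(n_replicates),
         baseline_range = baseline_range, sigma = sigma,
         programs = programs, shared_links = shared_links,
         shared_fraction = shared_fraction,
         platform_overlap = platform_overlap,
         effect_spread = effect_spread,
         truth_fc_threshold = truth_fc_threshold,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' Study-like two-tissue design
#'
#' Convenience constructor emulating the zonal cartilage study: an
#' articular tissue with superficial (SZ) and intermediate/deep (IDZ)
#' zones and a growth-plate tissue with resting (RZ), proliferative (PZ),
#' and hypertrophic (HZ) zones, each carrying one upregulation program per
#' zone. By default the IDZ program is linked to the RZ program and the SZ
#' program to the HZ program, planting the shared transcriptional programs
#' the analysis is designed to detect.
#'
#' @param n_genes Genes per platform (default 2000).
#' @param program_size Genes per zone program (default 150).
#' @param base_effect Base log2 effect of each program in its home zone
#'   (default `log2(2.5)`; per-gene magnitudes spread upward via
#'   `effect_spread`).
#' @param rho Shared fraction between linked programs (default 0.8).
#' @param seed Master seed.
#' @param ... Further arguments passed to [simulation_design()].
#' @return A `simulation_design` with tissues `articular` and
#'   `growth_plate`.
#' @export
study_design <- function(n_genes = 2000, program_size = 150,
                         base_effect = log2(2.5), rho = 0.8, seed = 1L, ...) {
  tissues <- list(articular = c("SZ", "IDZ"),
                  growth_plate = c("RZ", "PZ", "HZ"))
  programs <- list(
    articular = list(
      zone_program("prog_SZ", c(SZ = base_effect), size = program_size),
      zone_program("prog_IDZ", c(IDZ = base_effect), size = program_size)
    ),
    growth_plate = list(
      zone_program("prog_RZ", c(RZ = base_effect), size = program_size),
      zone_program("prog_PZ", c(PZ = base_effect), size = program_size),
      zone_program("prog_HZ", c(HZ = base_effect), size = program_size)
    )
  )
  links <- list(c("articular:prog_IDZ", "growth_plate:prog_RZ"),
                c("articular:prog_SZ", "growth_plate:prog_HZ"))
  simulation_design(tissues, n_genes = n_genes, programs = programs,
                    shared_links = links, shared_fraction = rho,
                    seed = seed, ...)
}

# ---- internal simulation machinery -----------------------------------------

# Build per-platform gene universes with the requested intersection
# fraction, sampling symbols from a shared synthetic pool.
build_universes <- function(design) {
  tis <- names(design$tissues)
  n <- design$n_genes
  if (length(tis) == 1) {
    pool <- sprintf("g%06d", seq_len(n))
    return(setNames(list(pool), tis))
  }
  o <- round(design$platform_overlap * n)
  pool <- sprintf("g%06d", seq_len(2L * n - o))
  pool <- sample(pool)
  shared <- pool[seq_len(o)]
  rest <- pool[-seq_len(o)]
  a_only <- rest[seq_len(n - o)]
  b_only <- rest[(n - o) + seq_len(n - o)]
  setNames(list(sort(c(shared, a_only)), sort(c(shared, b_only))), tis)
}

# Assign concrete gene sets (and per-gene effect multipliers) to every
# program, honoring cross-tissue shared links. Returns, per tissue, a list
# of programs with $genes and $multiplier filled, plus the shared tibble.
assign_program_genes <- function(design, universes) {
  tis <- names(design$tissues)
  progs <- design$programs
  assigned <- setNames(vector("list", length(tis)), tis)  # per-tissue used genes
  for (t in tis) assigned[[t]] <- character(0)
  out <- setNames(lapply(tis, function(t) list()), tis)
  shared_rows <- list()

  find_prog <- function(ref) {
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% names(progs)) {
      abort(paste0("bad shared link reference: ", ref))
    }
    idx <- which(vapply(progs[[parts[1]]], function(p) p$name, "") == parts[2])
    if (length(idx) != 1) abort(paste0("unknown program in link: ", ref))
    list(tissue = parts[1], idx = idx)
  }

  # shared genes first, drawn from the platform intersection
  if (length(design$shared_links) > 0 && length(tis) == 2) {
    inter <- intersect(universes[[1]], universes[[2]])
    for (link in design$shared_links) {
      a <- find_prog(link[1]); b <- find_prog(link[2])
      pa <- progs[[a$tissue]][[a$idx]]; pb <- progs[[b$tissue]][[b$idx]]
      s <- round(design$shared_fraction * min(pa$size, pb$size))
      avail <- setdiff(inter, c(assigned[[a$tissue]], assigned[[b$tissue]]))
      if (length(avail) < s) abort("intersection too small for requested shared programs.")
      genes <- sample(avail, s)
      out[[a$tissue]][[pa$name]] <- c(out[[a$tissue]][[pa$name]], genes)
      out[[b$tissue]][[pb$name]] <- c(out[[b$tissue]][[pb$name]], genes)
      assigned[[a$tissue]] <- c(assigned[[a$tissue]], genes)
      assigned[[b$tissue]] <- c(assigned[[b$tissue]], genes)
      shared_rows[[length(shared_rows) + 1]] <- tibble(
        tissue_a = a$tissue, program_a = pa$name,
        tissue_b = b$tissue, program_b = pb$name, gene = genes
      )
    }
  }

  # fill the remainder of every program from its own platform
  filled <- setNames(lapply(tis, function(t) list()), tis)
  for (t in names(progs)) {
    for (pr in progs[[t]]) {
      have <- out[[t]][[pr$name]] %||% character(0)
      need <- pr$size - length(have)
      if (!is.null(pr$genes)) {
        bad <- setdiff(pr$genes, universes[[t]])
        if (length(bad) > 0) abort(paste0("program '", pr$name, "' genes not on platform."))
        have <- pr$genes
        need <- 0
      }
      if (need > 0) {
        avail <- setdiff(universes[[t]], assigned[[t]])
        if (length(avail) < need) abort("universe too small for requested programs.")
        extra <- sample(avail, need)
        have <- c(have, extra)
        assigned[[t]] <- c(assigned[[t]], extra)
      }
      pr$genes <- have
      pr$multiplier <- setNames(runif(length(have), 1, design$effect_spread), have)
      filled[[t]][[pr$name]] <- pr
    }
  }
  shared <- if (length(shared_rows) > 0) purrr::list_rbind(shared_rows) else
    tibble(tissue_a = character(), program_a = character(),
           tissue_b = character(), program_b = character(), gene = character())
  list(programs = filled, shared = shared)
}

# Per-gene x per-zone planted log2 effect matrix for one tissue.
effect_matrix <- function(universe, zones, tissue_programs) {
  eff <- matrix(0, nrow = length(universe), ncol = length(zones),
                dimnames = list(universe, zones))
  for (pr in tissue_programs) {
    for (z in names(pr$effects)) {
      eff[pr$genes, z] <- eff[pr$genes, z] + pr$effects[[z]] * pr$multiplier[pr$genes]
    }
  }
  eff
}

# Truth bookkeeping: planted spatially regulated genes for every zone pair
# of a tissue, by direction, at the design's declared fold threshold.
planted_truth <- function(tissue, zones, eff, threshold) {
  lt <- log2(threshold)
  pairs <- utils::combn(zones, 2, simplify = FALSE)
  purrr::map(pairs, function(zp) {
    d <- eff[, zp[1]] - eff[, zp[2]]
    dplyr::bind_rows(
      tibble(tissue = tissue, zone_a = zp[1], zone_b = zp[2],
             direction = "up_in_a", gene = rownames(eff)[d >= lt]),
      tibble(tissue = tissue, zone_a = zp[1], zone_b = zp[2],
             direction = "up_in_b", gene = rownames(eff)[-d >= lt])
    )
  }) |> purrr::list_rbind()
}

simulate_tissue_matrix <- function(design, tissue, universe, tissue_programs,
                                   stream) {
  zones <- design$tissues[[tissue]]
  nr <- design$n_replicates
  eff <- effect_matrix(universe, zones, tissue_programs)
  with_seed(design$seed + stream, {
    mu <- runif(length(universe), design$baseline_range[1], design$baseline_range[2])
    cols <- as.vector(outer(seq_len(nr), zones,
                            function(r, z) paste(tissue, z, r, sep = "_")))
    zone_of <- rep(zones, each = nr)
    vals <- mu + eff[, zone_of, drop = FALSE] +
      matrix(rnorm(length(universe) * length(cols), sd = design$sigma),
             nrow = length(universe))
    dimnames(vals) <- list(universe, cols)
    samples <- tibble(sample_id = cols, tissue = tissue, zone = zone_of,
                      replicate = as.character(rep(seq_len(nr), times = length(zones))))
    list(expr = expr_matrix(vals, samples,
                            platform = paste0("sim_", tissue)),
         truth = planted_truth(tissue, zones, eff, design$truth_fc_threshold))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- exported simulation operations ----------------------------------------

#' Simulate one tissue's zonal expression dataset
#'
#' Generates a genes x (zones x replicates) log2 expression matrix:
#' value(g, sample in zone z) = baseline_g + planted effect_g(z) +
#' N(0, sigma^2), together with the ground truth listing exactly the genes
#' whose planted effect difference between a zone pair reaches the design's
#' declared fold threshold.
#'
#' @param design A [simulation_design()].
#' @param tissue Tissue label in the design.
#' @return List with `expr` (an [expr_matrix()]) and `truth` (object of
#'   class `zc_truth`: `$planted` tibble with columns `tissue`, `zone_a`,
#'   `zone_b`, `direction`, `gene`; `$shared` tibble, empty here).
#' @export
simulate_dataset <- function(design, tissue) {
  stopifnot(inherits(design, "simulation_design"))
  if (!tissue %in% names(design$tissues)) abort(paste0("unknown tissue: ", tissue))
  stream <- match(tissue, names(design$tissues))
  setup <- with_seed(design$seed, {
    universes <- build_universes(design)
    list(universes = universes,
         assignment = assign_program_genes(design, universes))
  })
  sim <- simulate_tissue_matrix(design, tissue, setup$universes[[tissue]],
                                setup$assignment$programs[[tissue]], stream)
  truth <- structure(list(planted = sim$truth,
                          shared = setup$assignment$shared[0, ]),
                     class = "zc_truth")
  list(expr = sim$expr, truth = truth)
}

#' Simulate a two-tissue, two-platform dataset pair
#'
#' Generates the cross-platform setting: two tissues measured on platforms
#' whose gene universes intersect in a `platform_overlap` fraction, with
#' linked zone programs sharing a `shared_fraction` (rho) of their genes.
#' The truth records per-tissue planted gene sets and, per linked program
#' pair, the shared genes.
#'
#' @param design A [simulation_design()] naming exactly two tissues.
#' @return List with `expr_a`, `expr_b` (the two [expr_matrix()] objects,
#'   in design tissue order) and `truth` (class `zc_truth` with `$planted`
#'   and `$shared` tibbles).
#' @export
simulate_tissue_pair <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  if (length(design$tissues) != 2) abort("design must name exactly two tissues.")
  tis <- names(design$tissues)
  setup <- with_seed(design$seed, {
    universes <- build_universes(design)
    list(universes = universes,
         assignment = assign_program_genes(design, universes))
  })
  sims <- purrr::imap(setNames(tis, tis), function(t, nm) {
    simulate_tissue_matrix(design, t, setup$universes[[t]],
                           setup$assignment$programs[[t]],
                           stream = match(t, tis))
  })
  truth <- structure(
    list(planted = purrr::list_rbind(purrr::map(sims, "truth")),
         shared = setup$assignment$shared),
    class = "zc_truth"
  )
  list(expr_a = sims[[1]]$expr, expr_b = sims[[2]]$expr, truth = truth)
}

#' @export
print.zc_truth <- function(x, ...) {
  cat(sprintf("<zc_truth> %d planted (tissue, pair, direction, gene) rows; %d shared genes across %d link(s)\n",
              nrow(x$planted), nrow(x$shared),
              nrow(dplyr::distinct(x$shared[c("program_a", "program_b")]))))
  invisible(x)
}

#' Simulate a probe-level matrix from gene values
#'
#' Each gene's expression profile is replicated over `n_probes_per_gene`
#' probes: probe value = gene value + probe offset + N(0, noise_sd), the
#' additive model median polish assumes. Values are on the log2 scale.
#'
#' @param gene_values Gene x sample numeric matrix (log2 scale) with
#'   dimnames.
#' @param n_probes_per_gene Probes per gene (>= 1).
#' @param probe_offsets Numeric vector of probe affinity offsets, length
#'   `n_probes_per_gene` (recycled across genes) or one per probe row;
#'   default drawn N(0, 0.3).
#' @param noise_sd Gaussian probe noise sd (log2 units).
#' @param seed Integer seed.
#' @return List with `values` (probe x sample matrix) and `probe_gene`
#'   (tibble `probe_id`, `gene`).
#' @export
simulate_probe_matrix <- function(gene_values, n_probes_per_gene,
                                  probe_offsets = NULL, noise_sd = 0.1,
                                  seed = 1L) {
  gene_values <- as.matrix(gene_values)
  if (n_probes_per_gene < 1) abort("`n_probes_per_gene` must be >= 1.")
  n_g <- nrow(gene_values)
  n_p <- n_g * n_probes_per_gene
  with_seed(seed, {
    if (is.null(probe_offsets)) {
      probe_offsets <- rnorm(n_probes_per_gene, sd = 0.3)
    }
    offsets <- if (length(probe_offsets) == n_probes_per_gene) {
      rep(probe_offsets, times = n_g)
    } else if (length(probe_offsets) == n_p) {
      probe_offsets
    } else {
      abort("`probe_offsets` must have length n_probes_per_gene or one per probe.")
    }
    gene_of <- rep(rownames(gene_values), each = n_probes_per_gene)
    probe_id <- paste0(gene_of, "_p", rep(seq_len(n_probes_per_gene), times = n_g))
    vals <- gene_values[gene_of, , drop = FALSE] + offsets +
      matrix(rnorm(n_p * ncol(gene_values), sd = noise_sd), nrow = n_p)
    rownames(vals) <- probe_id
    list(values = vals, probe_gene = tibble(probe_id = probe_id, gene = gene_of))
  })
}

#' Simulate a qPCR CT table
#'
#' Generates triplicate threshold-cycle measurements per (animal, zone,
#' gene) under the standard relation that CT drops one cycle per log2 unit
#' of expression: ct = base CT - planted log2 effect(zone) + N(0,
#' noise_sd). The reference (housekeeping) gene is measured for every
#' (animal, zone) at its own base CT.
#'
#' @param effect_profile Named list: gene -> named numeric vector of log2
#'   fold versus the reference zone, one entry per zone (0 for the
#'   reference zone). Must include an entry for `reference_gene`
#'   (typically all zeros).
#' @param n_animals Biological replicates (>= 2; default 4).
#' @param noise_sd Well-to-well CT noise in cycles (default 0.3).
#' @param seed Integer seed.
#' @param reference_gene Housekeeping gene symbol (default `"Rn18s"`).
#' @param base_ct Base CT of target genes (default 25).
#' @param ref_ct Base CT of the reference gene (default 12; abundant rRNA).
#' @param n_replicates Technical replicates per well condition (default 3).
#' @return A qPCR tibble (`animal`, `zone`, `gene`, `replicate`, `ct`)
#'   suitable for [relative_expression_table()].
#' @export
simulate_qpcr <- function(effect_profile, n_animals = 4, noise_sd = 0.3,
                          seed = 1L, reference_gene = "Rn18s",
                          base_ct = 25, ref_ct = 12, n_replicates = 3) {
  if (n_animals < 2) abort("`n_animals` must be >= 2.")
  if (!reference_gene %in% names(effect_profile)) {
    abort(paste0("`effect_profile` must include the reference gene '",
                 reference_gene, "'."))
  }
  zones <- names(effect_profile[[1]])
  for (g in names(effect_profile)) {
    if (!setequal(names(effect_profile[[g]]), zones)) {
      abort("all genes must profile the same zones.")
    }
  }
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      animal = paste0("animal_", seq_len(n_animals)),
      zone = zones,
      gene = names(effect_profile),
      replicate = seq_len(n_replicates)
    )
    base <- ifelse(grid$gene == reference_gene, ref_ct, base_ct)
    eff <- purrr::map2_dbl(grid$gene, grid$zone,
                           function(g, z) effect_profile[[g]][[z]])
    grid$ct <- base - eff + rnorm(nrow(grid), sd = noise_sd)
    grid
  })
}
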