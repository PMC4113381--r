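test_that("simulated matrices have the declared shape and are finite", {
  d <- simulation_design(list(t1 = c("Z1", "Z2")), n_genes = 1000,
                         n_replicates = 4, seed = 3)
  sim <- simulate_dataset(d, "t1")
  expect_equal(dim(sim$expr), c(1000L, 8L))
  expect_true(all(is.finite(sim$expr$values)))
  expect_equal(unname(table(sim$expr$samples$zone)), c(4L, 4L),
               ignore_attr = TRUE)
})

test_that("a design with no programs plants no truth", {
  d <- simulation_design(list(t1 = c("Z1", "Z2")), n_genes = 200, seed = 5)
  sim <- simulate_dataset(d, "t1")
  expect_equal(nrow(sim$truth$planted), 0L)
})

test_that("simulation is deterministic for a fixed design and seed", {
  d <- study_design(n_genes = 300, program_size = 40, seed = 11)
  s1 <- simulate_tissue_pair(d)
  s2 <- simulate_tissue_pair(d)
  expect_identical(s1$expr_a$values, s2$expr_a$values)
  expect_identical(s1$expr_b$values, s2$expr_b$values)
  expect_identical(s1$truth$planted, s2$truth$planted)
  expect_identical(s1$truth$shared, s2$truth$shared)
})

test_that("unknown tissues and bad designs are rejected", {
  d <- simulation_design(list(t1 = c("Z1", "Z2")), n_genes = 100)
  expect_error(simulate_dataset(d, "nope"), "unknown tissue")
  expect_error(simulate_tissue_pair(d), "exactly two")
  expect_error(simulation_design(list(t1 = c("Z1", "Z2")), sigma = 0),
               "sigma")
  expect_error(simulation_design(list(t1 = c("Z1", "Z2")), n_replicates = 1),
               "n_replicates")
})

test_that("platform overlap and shared fractions are realized", {
  d <- study_design(n_genes = 500, program_size = 60, rho = 0.8, seed = 2,
                    platform_overlap = 0.9)
  sim <- simulate_tissue_pair(d)
  ua <- rownames(sim$expr_a$values); ub <- rownames(sim$expr_b$values)
  expect_lte(abs(length(intersect(ua, ub)) - 0.9 * 500), 1)
  shared_per_link <- dplyr::count(sim$truth$shared, program_a)
  expect_true(all(abs(shared_per_link$n - 0.8 * 60) <= 1))

  # rho = 0: independence null, no shared genes
  d0 <- study_design(n_genes = 500, program_size = 60, rho = 0, seed = 2)
  expect_equal(nrow(simulate_tissue_pair(d0)$truth$shared), 0L)

  # rho = 1 with equal program sizes: the full program is shared
  d1 <- study_design(n_genes = 500, program_size = 60, rho = 1, seed = 2)
  s1 <- simulate_tissue_pair(d1)
  expect_true(all(dplyr::count(s1$truth$shared, program_a)$n == 60))

  # platform_overlap = 1: identical gene universes
  dfull <- study_design(n_genes = 400, program_size = 50, seed = 4,
                        platform_overlap = 1)
  sfull <- simulate_tissue_pair(dfull)
  expect_setequal(rownames(sfull$expr_a$values), rownames(sfull$expr_b$values))
})

test_that("truth bookkeeping is self-consistent", {
  d <- study_design(n_genes = 500, program_size = 60, seed = 9)
  sim <- simulate_tissue_pair(d)
  planted_a <- sim$truth$planted$gene[sim$truth$planted$tissue == "articular"]
  planted_b <- sim$truth$planted$gene[sim$truth$planted$tissue == "growth_plate"]
  expect_true(all(sim$truth$shared$gene %in% planted_a))
  expect_true(all(sim$truth$shared$gene %in% planted_b))
  # planted genes live on the right platform
  expect_true(all(planted_a %in% rownames(sim$expr_a$values)))
  expect_true(all(planted_b %in% rownames(sim$expr_b$values)))
})

test_that("null genes give uniform ANOVA p-values", {
  d <- simulation_design(list(t1 = c("Z1", "Z2")), n_genes = 1000, seed = 21)
  sim <- simulate_dataset(d, "t1")
  de <- call_spatially_regulated(sim$expr, "Z1", "Z2")
  ks <- stats::ks.test(de$p_raw, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("probe-level simulation follows the additive model", {
  gv <- matrix(seq_len(12), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  # zero noise, zero offsets: probe rows equal their gene's values
  pm <- simulate_probe_matrix(gv, n_probes_per_gene = 4,
                              probe_offsets = rep(0, 4), noise_sd = 0, seed = 1)
  for (g in rownames(gv)) {
    rows <- pm$probe_gene$probe_id[pm$probe_gene$gene == g]
    expect_equal(unname(pm$values[rows, ]),
                 matrix(rep(gv[g, ], each = 4), nrow = 4), ignore_attr = TRUE)
  }
  # zero noise with offsets: median polish recovers gene profiles up to a
  # constant
  pm2 <- simulate_probe_matrix(gv, 4, probe_offsets = c(-1, 0, 0.5, 2),
                               noise_sd = 0, seed = 1)
  summ <- summarize_probes(pm2$values, pm2$probe_gene)
  for (g in rownames(gv)) {
    expect_equal(diff(summ[g, ]), diff(gv[g, ]), tolerance = 1e-8)
  }
  # seeded reproducibility
  a <- simulate_probe_matrix(gv, 3, noise_sd = 0.2, seed = 7)
  b <- simulate_probe_matrix(gv, 3, noise_sd = 0.2, seed = 7)
  expect_identical(a$values, b$values)
})

test_that("qPCR simulation realizes planted log2 effects exactly at zero noise", {
  prof <- list(
    Rn18s = c(SZ = 0, IDZ = 0),
    Prg4 = c(SZ = 1, IDZ = 0)
  )
  tab <- simulate_qpcr(prof, n_animals = 3, noise_sd = 0, seed = 1)
  rel <- relative_expression_table(tab, reference_gene = "Rn18s")
  sz <- rel$rel_expr[rel$zone == "SZ"]
  idz <- rel$rel_expr[rel$zone == "IDZ"]
  expect_equal(sz / idz, rep(2, 3))

  # zero effects, zero noise: flat across zones
  prof0 <- list(Rn18s = c(SZ = 0, IDZ = 0), Gene1 = c(SZ = 0, IDZ = 0))
  rel0 <- relative_expression_table(simulate_qpcr(prof0, 2, 0, seed = 2))
  expect_equal(length(unique(round(rel0$rel_expr, 9))), 1L)

  # determinism and input validation
  expect_identical(simulate_qpcr(prof, 3, 0.3, seed = 5),
                   simulate_qpcr(prof, 3, 0.3, seed = 5))
  expect_error(simulate_qpcr(prof["Prg4"], 3, 0.3, seed = 1),
               "reference gene")
  expect_error(simulate_qpcr(prof, n_animals = 1, seed = 1), "n_animals")
})
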