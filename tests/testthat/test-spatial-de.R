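test_that("one-way ANOVA matches the textbook computation and aov", {
  res <- one_way_anova_p(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(res$statistic, 1.5)
  expect_equal(res$p_value, pf(1.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$p_value, 0.288, tolerance = 1e-2)

  # cross-check against stats::aov on random groups
  set.seed(6)
  for (i in 1:5) {
    groups <- lapply(sample(2:4, sample(2:4, 1), replace = TRUE) + 1, rnorm)
    y <- unlist(groups)
    g <- factor(rep(seq_along(groups), lengths(groups)))
    ref <- anova(aov(y ~ g))
    res <- one_way_anova_p(groups)
    expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate cases follow the declared conventions", {
  expect_equal(one_way_anova_p(list(c(1, 1), c(1, 1)))[c("statistic", "p_value")],
               list(statistic = 0, p_value = 1))
  expect_warning(res <- one_way_anova_p(list(c(1, 1), c(2, 2))), "zero residual")
  expect_equal(res$p_value, 0)
  expect_true(res$degenerate)
  expect_error(one_way_anova_p(list(1, c(2, 3))), "at least 2")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(4, 8, 0.4); b <- rnorm(4, 8.5, 0.4)
    f <- one_way_anova_p(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(f$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("vectorized per-gene ANOVA agrees with the scalar path", {
  set.seed(8)
  vals <- matrix(rnorm(50 * 8, 8, 0.35), nrow = 50,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  group <- rep(c("A", "B"), each = 4)
  fit <- zonecor:::row_anova(vals, group)
  for (i in c(1, 17, 50)) {
    ref <- one_way_anova_p(list(vals[i, 1:4], vals[i, 5:8]))
    expect_equal(fit$statistic[i], ref$statistic, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(fit$p_value[i], ref$p_value, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance
  set.seed(9)
  p <- runif(40)
  perm <- sample(40)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("fold change reproduces printed raw-signal ratios", {
  fc <- fold_change(940, 39)
  expect_equal(fc$fold_change, 24.1, tolerance = 0.01)
  expect_equal(fc$direction, "up_in_a")
  expect_equal(fc$fold_change_int, 24)
  rev <- fold_change(39, 940)
  expect_equal(rev$fold_change, fc$fold_change)
  expect_equal(rev$direction, "up_in_b")
  eq <- fold_change(100, 100)
  expect_equal(eq$fold_change, 1)
  expect_equal(eq$direction, "none")
  expect_error(fold_change(-1, 5), "positive")
})

test_that("the calling rule requires both the fold and the FDR threshold", {
  # gene 1: huge significance but 1.9-fold -> not called
  # gene 2: > 2-fold and significant -> called, up in zone a
  set.seed(10)
  lfc19 <- log2(1.9)
  vals <- rbind(
    g_sub2fold = c(8 + lfc19 + rnorm(4, 0, 0.01), 8 + rnorm(4, 0, 0.01)),
    g_strong = c(log2(940) + rnorm(4, 0, 0.05), log2(39) + rnorm(4, 0, 0.05)),
    g_null = rnorm(8, 8, 0.3)
  )
  colnames(vals) <- paste0("s", 1:8)
  x <- toy_expr(vals, zones = rep(c("SZ", "IDZ"), each = 4))
  de <- call_spatially_regulated(x, "SZ", "IDZ")
  expect_false(de$called[de$gene == "g_sub2fold"])
  expect_lt(de$q_fdr[de$gene == "g_sub2fold"], 0.01)
  expect_true(de$called[de$gene == "g_strong"])
  expect_equal(de$direction[de$gene == "g_strong"], "up_in_a")
  expect_equal(de$fold_change[de$gene == "g_strong"], 24.1, tolerance = 0.2)
})

test_that("zone relabeling flips direction but not the calls", {
  d <- study_design(n_genes = 300, program_size = 40, seed = 12)
  sim <- simulate_dataset(d, "articular")
  de_ab <- call_spatially_regulated(sim$expr, "SZ", "IDZ")
  de_ba <- call_spatially_regulated(sim$expr, "IDZ", "SZ")
  expect_equal(de_ab$called, de_ba$called)
  expect_equal(de_ab$p_raw, de_ba$p_raw, tolerance = 1e-12)
  flip <- c(up_in_a = "up_in_b", up_in_b = "up_in_a", none = "none")
  expect_equal(unname(flip[de_ab$direction]), de_ba$direction)
})

test_that("directional lists partition the called set", {
  d <- study_design(n_genes = 400, program_size = 60, seed = 13)
  sim <- simulate_dataset(d, "growth_plate")
  de <- call_spatially_regulated(sim$expr, "RZ", "HZ")
  lists <- directional_gene_lists(de)
  expect_length(intersect(lists[[1]], lists[[2]]), 0)
  expect_setequal(c(lists[[1]], lists[[2]]), de$gene[de$called])
})

test_that("pure noise yields essentially no calls under the full rule", {
  d <- simulation_design(list(t1 = c("Z1", "Z2")), n_genes = 200,
                         sigma = 0.35, seed = 14)
  sim <- simulate_dataset(d, "t1")
  de <- call_spatially_regulated(sim$expr, "Z1", "Z2")
  expect_lte(sum(de$q_fdr < 0.05), 10)
  expect_lte(sum(de$called), 2)
})
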