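test_that("universe intersection is case-insensitive and deterministic", {
  expect_equal(intersect_universe(c("Prg4", "Bmp3"), c("PRG4", "Sfrp5")), "PRG4")
  expect_length(intersect_universe(c("a", "b"), c("c", "d")), 0)
  a <- c("g1", "g2"); b <- c("g3", "g2", "g1")
  expect_equal(intersect_universe(a, b), c("G1", "G2"))  # A subset of B -> A
})

test_that("overlap chi-square matches hand computations", {
  # k exactly at the chance expectation: chi2 = 0, p = 1, no direction
  cfg <- lists_for_counts(100, 10, 10, 1)
  r <- directional_overlap_test(cfg$a, cfg$b, cfg$universe)
  expect_equal(r$expected, 1)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_raw, 1)
  expect_equal(r$direction, "none")

  # enrichment example: expected 5, all four cells contribute
  cfg <- lists_for_counts(1000, 100, 50, 20)
  r <- directional_overlap_test(cfg$a, cfg$b, cfg$universe)
  expect_equal(r$expected, 5)
  expect_equal(r$chi2, chi2_oracle(1000, 100, 50, 20), tolerance = 1e-9)
  expect_equal(r$chi2, 52.63, tolerance = 0.01)
  expect_equal(r$direction, "more_than_chance")

  # total overlap of two half-universe lists: every cell deviates by 25
  cfg <- lists_for_counts(100, 50, 50, 50)
  r <- directional_overlap_test(cfg$a, cfg$b, cfg$universe)
  expect_equal(r$chi2, 100)
  expect_equal(r$direction, "more_than_chance")
})

test_that("overlap chi-square equals oracles on random configurations", {
  set.seed(15)
  for (i in 1:250) {
    N <- sample(20:400, 1)
    n_a <- sample(seq_len(N - 1), 1)
    n_b <- sample(seq_len(N - 1), 1)
    k <- sample(max(0, n_a + n_b - N):min(n_a, n_b), 1)
    cfg <- lists_for_counts(N, n_a, n_b, k)
    r <- directional_overlap_test(cfg$a, cfg$b, cfg$universe)
    expect_equal(r$chi2, chi2_oracle(N, n_a, n_b, k), tolerance = 1e-9)
    # independent reference: Pearson chi-square without continuity correction
    tab <- matrix(c(k, n_a - k, n_b - k, N - n_a - n_b + k), nrow = 2)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(r$p_raw, ref$p.value, tolerance = 1e-9)
    # two-proportion z-test identity: z^2 = chi2
    p_pool <- n_b / N
    p1 <- k / n_a; p2 <- (n_b - k) / (N - n_a)
    z <- (p1 - p2) / sqrt(p_pool * (1 - p_pool) * (1 / n_a + 1 / (N - n_a)))
    expect_equal(z^2, r$chi2, tolerance = 1e-9)
  }
})

test_that("overlap test is symmetric in its two lists", {
  cfg <- lists_for_counts(500, 60, 140, 30)
  r1 <- directional_overlap_test(cfg$a, cfg$b, cfg$universe)
  r2 <- directional_overlap_test(cfg$b, cfg$a, cfg$universe)
  expect_equal(r1[c("N", "k", "expected", "chi2", "p_raw")],
               r2[c("N", "k", "expected", "chi2", "p_raw")])
})

test_that("degenerate margins are flagged instead of tested", {
  uni <- sprintf("G%03d", 1:50)
  r <- directional_overlap_test(character(0), uni[1:10], uni)
  expect_true(r$degenerate)
  expect_true(is.na(r$p_raw))
  expect_equal(r$direction, "none")
  r2 <- directional_overlap_test(uni, uni[1:10], uni)  # n_a = N
  expect_true(r2$degenerate)
})

test_that("Holm-Sidak adjustment matches the closed form and its bounds", {
  expect_equal(holm_sidak_adjust(0.02), 0.02)
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)), c(0.0199, 0.04))
  expect_equal(holm_sidak_adjust(c(0, 0, 0)), c(0, 0, 0))
  expect_error(holm_sidak_adjust(c(0.1, -0.2)), "\\[0, 1\\]")
  # returned in input order
  p <- c(0.04, 0.01)
  expect_equal(holm_sidak_adjust(p), c(0.04, 0.0199))
  # bounds: raw <= Holm-Sidak <= Holm(-Bonferroni) <= Bonferroni
  set.seed(16)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    hs <- holm_sidak_adjust(p)
    expect_true(all(hs >= p - 1e-12))
    expect_true(all(hs <= p.adjust(p, "holm") + 1e-12))
    expect_true(all(hs <= p.adjust(p, "bonferroni") + 1e-12))
  }
})

test_that("an all-empty family is reported as 12 degenerate tests", {
  uni <- sprintf("G%03d", 1:100)
  empty <- setNames(rep(list(character(0)), 2), c("A>B", "B>A"))
  empty6 <- setNames(rep(list(character(0)), 6),
                     c("R>P", "P>R", "R>H", "H>R", "P>H", "H>P"))
  fam <- all_pairs_correspondence(empty, empty6, uni)
  expect_equal(nrow(fam), 12L)
  expect_true(all(fam$degenerate))
  expect_true(all(fam$direction == "none"))
})

test_that("planted shared programs are recovered as enriched overlaps", {
  d <- study_design(n_genes = 1000, program_size = 100, rho = 0.8, seed = 17)
  sim <- simulate_tissue_pair(d)
  uni <- intersect_universe(rownames(sim$expr_a$values),
                            rownames(sim$expr_b$values))
  la <- all_directional_lists(sim$expr_a)
  lb <- all_directional_lists(sim$expr_b)
  fam <- all_pairs_correspondence(la, lb, uni)
  # the two linked program pairs: IDZ-up ~ RZ-up and SZ-up ~ HZ-up
  hit1 <- fam[fam$list_a == "IDZ>SZ" & fam$list_b == "RZ>PZ", ]
  hit2 <- fam[fam$list_a == "SZ>IDZ" & fam$list_b == "HZ>RZ", ]
  expect_equal(hit1$direction, "more_than_chance")
  expect_equal(hit2$direction, "more_than_chance")
  expect_gt(hit1$k, hit1$expected * 3)
})

test_that("marker localization counts markers inside directional lists", {
  set.seed(18)
  # build a matrix where 3 of 6 markers are planted up in SZ
  genes <- c(paste0("mk", 1:6), paste0("bg", 1:44))
  eff <- c(rep(1.5, 3), rep(0, 3), rep(0, 44))
  vals <- matrix(8 + rnorm(50 * 8, 0, 0.1), nrow = 50,
                 dimnames = list(genes, paste0("s", 1:8)))
  vals[, 1:4] <- vals[, 1:4] + eff
  x <- toy_expr(vals, zones = rep(c("SZ", "IDZ"), each = 4))
  de <- call_spatially_regulated(x, "SZ", "IDZ")
  markers <- tibble::tibble(zone = "PZ", gene = paste0("mk", 1:6))
  loc <- marker_localization(markers, de, rownames(vals))
  up_sz <- loc[loc$direction_list == "SZ>IDZ", ]
  expect_equal(up_sz$K, 6L)
  expect_equal(up_sz$k_up, 3L)
  expect_equal(up_sz$direction, "more_than_chance")
  # empty opposite list: zero markers, degenerate margin
  up_idz <- loc[loc$direction_list == "IDZ>SZ", ]
  expect_equal(up_idz$k_up, 0L)
  # markers identical to the up-list: maximal overlap
  markers2 <- tibble::tibble(zone = "X", gene = de$gene[de$called])
  loc2 <- marker_localization(markers2, de, rownames(vals))
  row2 <- loc2[loc2$direction_list == "SZ>IDZ", ]
  expect_equal(row2$k_up, row2$K)
  expect_equal(row2$direction, "more_than_chance")
  # marker set off the universe errors with its name
  expect_error(marker_localization(tibble::tibble(zone = "Z", gene = "nope"),
                                   de, rownames(vals)), "'Z'")
})
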