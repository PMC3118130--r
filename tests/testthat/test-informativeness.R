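test_that("delta averages absolute frequency differences over pairs", {
  same <- freq_panel(matrix(0.4, 3, 1), pop = c("A", "B", "C"), n = 10,
                     loci = "L1")
  expect_equal(delta_informativeness(same)$score, 0)

  fixed <- freq_panel(matrix(c(0, 1), 2, 1), pop = c("A", "B"), n = 10,
                      loci = "L1")
  expect_equal(delta_informativeness(fixed)$score, 1)

  tri <- freq_panel(matrix(c(0.2, 0.5, 0.8), 3, 1), pop = c("A", "B", "C"),
                    n = 10, loci = "L1")
  expect_equal(delta_informativeness(tri)$score, mean(c(0.3, 0.6, 0.3)))

  expect_error(delta_informativeness(
    freq_panel(matrix(0.5, 1, 1), pop = "A", n = 5, loci = "L1")),
    "at least 2")
})

test_that("Wright's FST matches hand computation and handles fixation", {
  fixed <- freq_panel(matrix(c(0, 1), 2, 1), pop = c("A", "B"), n = 10,
                      loci = "L1")
  expect_equal(wright_fst(fixed, "global")$score, 1)

  equal <- freq_panel(matrix(0.3, 3, 1), pop = c("A", "B", "C"), n = 10,
                      loci = "L1")
  expect_equal(wright_fst(equal, "global")$score, 0)

  two <- freq_panel(matrix(c(0.2, 0.8), 2, 1), pop = c("A", "B"), n = 10,
                    loci = "L1")
  expect_equal(wright_fst(two, "global")$score, 0.36)
})

test_that("Wright's global and pairwise modes coincide for two populations", {
  sim <- simulate_panel(sim_config(n_breeds = 2, n_loci = 200, seed = 21))
  expect_equal(wright_fst(sim$panel, "global")$score,
               wright_fst(sim$panel, "pairwise")$score)
  expect_equal(wc_fst(sim$panel, "global")$score,
               wc_fst(sim$panel, "pairwise")$score)
})

test_that("W&C's FST reproduces its algebraic small-sample limits", {
  # identical sample frequencies, equal sizes n: FST = -1/(n-1)
  for (n in c(5, 10, 30)) {
    pan <- freq_panel(matrix(c(0.4, 0.4), 2, 1), pop = c("A", "B"),
                      n = c(n, n), loci = "L1")
    expect_equal(wc_fst(pan, "global")$score, -1 / (n - 1))
  }
  # opposite fixation: MSG = 0, FST = 1
  fixed <- freq_panel(matrix(c(0, 1), 2, 1), pop = c("A", "B"), n = 10,
                      loci = "L1")
  expect_equal(wc_fst(fixed, "global")$score, 1)
  # monomorphic everywhere for the same allele: degenerate, scored 0
  mono <- freq_panel(matrix(c(1, 1), 2, 1), pop = c("A", "B"), n = 10,
                     loci = "L1")
  expect_warning(r <- wc_fst(mono, "global"), "degenerate")
  expect_equal(r$score, 0)
})

test_that("W&C's FST agrees with an independently coded oracle", {
  sim <- simulate_panel(sim_config(n_breeds = 5, n_loci = 400,
                                   breed_fst = c(0.02, 0.05, 0.1, 0.2, 0.3),
                                   sample_sizes = c(10, 15, 20, 30, 48),
                                   seed = 22))
  panel <- sim$panel
  loci <- panel_loci(panel)
  p <- as.matrix(panel[, loci])
  got <- wc_fst(panel, "global")
  want <- vapply(seq_along(loci), function(j) {
    wc_oracle_locus(p[, j], panel$n)
  }, numeric(1))
  expect_equal(got$score[match(loci, got$locus)], want, tolerance = 1e-10)
  expect_true(all(got$score <= 1))
  expect_true(any(want < 0))  # negatives retained
})

test_that("PCA scores equal squared-loading sums from a direct eigendecomposition", {
  m <- matrix(c(0.10, 0.80, 0.35, 0.62, 0.50, 0.05,
                0.20, 0.75, 0.30, 0.40, 0.55, 0.15,
                0.90, 0.20, 0.45, 0.35, 0.60, 0.10,
                0.85, 0.25, 0.40, 0.70, 0.45, 0.20),
              nrow = 4, byrow = TRUE)
  pan <- freq_panel(m, pop = paste0("P", 1:4), n = 20,
                    loci = paste0("L", 1:6))
  r <- pca_informativeness(pan, n_random_matrices = 50, seed = 99)
  k <- attr(r, "n_significant")
  expect_gte(k, 1)

  xc <- scale(m, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(xc) / (nrow(m) - 1))   # 6x6 covariance of loci
  want <- rowSums(eg$vectors[, seq_len(k), drop = FALSE]^2)
  expect_equal(r$score[match(paste0("L", 1:6), r$locus)], want,
               tolerance = 1e-10)
})

test_that("PCA scoring is invariant to row and column order and to symmetry", {
  sim <- simulate_panel(sim_config(n_breeds = 5, n_loci = 60, seed = 23))
  pan <- sim$panel
  r1 <- pca_informativeness(pan, n_random_matrices = 30, seed = 7)
  perm_rows <- pan[sample(nrow(pan)), ]
  perm_cols <- pan[, c("pop", "n", sample(panel_loci(pan)))]
  r2 <- pca_informativeness(as_freq_panel(perm_rows),
                            n_random_matrices = 30, seed = 7)
  r3 <- pca_informativeness(as_freq_panel(perm_cols),
                            n_random_matrices = 30, seed = 7)
  expect_equal(r1, r2)
  expect_equal(r1[, c("locus", "score")], r3[, c("locus", "score")])

  # a locus constant across populations has zero loading everywhere
  m <- as.matrix(pan[, panel_loci(pan)])
  m[, 1] <- 0.42
  pan_const <- freq_panel(m, pop = pan$pop, n = pan$n,
                          loci = panel_loci(pan))
  rc <- pca_informativeness(pan_const, n_random_matrices = 30, seed = 7)
  expect_equal(rc$score[rc$locus == panel_loci(pan)[1]], 0)

  # duplicated locus columns receive equal scores
  m2 <- cbind(m[, 1:10], dup = m[, 10])
  pan_dup <- freq_panel(m2, pop = pan$pop, n = pan$n,
                        loci = c(colnames(m)[1:10], "Ldup"))
  rd <- pca_informativeness(pan_dup, n_random_matrices = 30, seed = 7)
  expect_equal(rd$score[rd$locus == "Ldup"],
               rd$score[rd$locus == colnames(m)[10]])
})

test_that("ranking is a deterministic total order", {
  sc <- tibble::tibble(locus = c("a", "b", "c"), score = c(0.1, 0.9, 0.5))
  expect_equal(rank_markers(sc)$locus, c("b", "c", "a"))

  tied <- tibble::tibble(locus = c("b", "a"), score = c(0.5, 0.5))
  expect_equal(rank_markers(tied)$locus, c("a", "b"))

  r <- rank_markers(sc)
  expect_equal(rank_markers(r)$locus, r$locus)  # idempotent

  expect_error(rank_markers(tibble::tibble(locus = c("a", "b"),
                                           score = c(NaN, 1))),
               "non-finite.*a")
})

test_that("ranking agreement statistics behave at the extremes", {
  sim <- simulate_panel(sim_config(n_breeds = 3, n_loci = 100, seed = 24))
  r1 <- delta_informativeness(sim$panel)
  expect_equal(compare_rankings(r1, r1, top_n = 30)$rho, 1)
  expect_equal(compare_rankings(r1, r1, top_n = 30)$overlap, 30)

  rev <- rank_markers(tibble::tibble(locus = r1$locus, score = -r1$score))
  expect_equal(compare_rankings(r1, rev, top_n = 30)$rho, -1)

  half <- 50
  s1 <- setNames(c(rep(1, half), rep(0, half)), paste0("x", 1:100))
  s2 <- setNames(c(rep(0, half), rep(1, half)), paste0("x", 1:100))
  expect_equal(compare_rankings(rank_markers(s1), rank_markers(s2),
                                top_n = half)$overlap, 0)

  r_other <- delta_informativeness(
    simulate_panel(sim_config(n_breeds = 3, n_loci = 90, seed = 25))$panel)
  expect_error(compare_rankings(r1, r_other), "different locus sets")
})

test_that("score bounds hold on simulated panels", {
  panel <- std_sim()$panel
  expect_true(all(dplyr::between(delta_informativeness(panel)$score, 0, 1)))
  expect_true(all(dplyr::between(wright_fst(panel, "global")$score, 0, 1)))
  expect_true(all(wc_fst(panel, "pairwise")$score <= 1))
})
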