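test_that("clamped fixation loci give the closed-form log-likelihoods", {
  pan <- freq_panel(matrix(c(1, 0), 2, 1), pop = c("A", "B"), n = 10,
                    loci = "L1")
  gt <- geno_table(matrix(2L, 1, 1), indiv = "x", pop = "A", loci = "L1")
  ll <- genotype_loglik(gt, pan)
  expect_equal(ll["x", "A"], 2 * log10(0.99999), tolerance = 1e-12)
  expect_equal(ll["x", "B"], 2 * log10(1e-5), tolerance = 1e-12)
  fit <- assign_individuals(gt, pan)
  expect_equal(fit$result$llr, 10 + 2 * log10(0.99999), tolerance = 1e-9)
})

test_that("a heterozygote at p = 0.5 carries no discriminating information", {
  pan <- freq_panel(matrix(0.5, 3, 1), pop = c("A", "B", "C"), n = 10,
                    loci = "L1")
  gt <- geno_table(matrix(1L, 1, 1), indiv = "x", pop = "A", loci = "L1")
  ll <- genotype_loglik(gt, pan)
  expect_equal(as.numeric(ll), rep(log10(0.5), 3))
})

test_that("multilocus log-likelihood is additive over loci", {
  pan <- toy_panel()
  gt <- geno_table(matrix(c(2L, 1L, 0L), 1, 3), indiv = "x", pop = "A",
                   loci = c("L1", "L2", "L3"))
  full <- genotype_loglik(gt, pan)
  parts <- sapply(c("L1", "L2", "L3"), function(l) {
    genotype_loglik(gt, pan, loci = l)   # 2 populations x 1 locus each
  })
  expect_equal(as.numeric(full), unname(rowSums(parts)), tolerance = 1e-12)
})

test_that("log-likelihoods match the brute-force product oracle", {
  sim <- simulate_panel(sim_config(n_breeds = 3, n_loci = 5,
                                   sample_sizes = 8, seed = 31,
                                   missing_rate = 0.1))
  ll <- genotype_loglik(sim$gt, sim$panel)
  want <- loglik_oracle(sim$gt, sim$panel, panel_loci(sim$panel))
  expect_equal(ll, want, tolerance = 1e-12)
})

test_that("stringency thresholds use strict inequality on the LLR", {
  ll <- matrix(c(0, -2.5, -4, -10), 1, 4,
               dimnames = list("x", c("A", "B", "C", "D")))
  res <- snpanel:::assign_from_loglik(ll, "A", c(0, 1, 2, 3))
  expect_equal(res$llr, 2.5)
  expect_equal(unlist(res[paste0("correct_", 0:3)], use.names = FALSE),
               c(TRUE, TRUE, TRUE, FALSE))
  # llr exactly equal to the threshold fails
  res2 <- snpanel:::assign_from_loglik(
    matrix(c(0, -1), 1, 2, dimnames = list("x", c("A", "B"))), "A", c(0, 1))
  expect_false(res2$correct_1)
  expect_true(res2$correct_0)
})

test_that("assignment against a single reference population is an error", {
  pan <- freq_panel(matrix(0.5, 1, 1), pop = "A", n = 10, loci = "L1")
  gt <- geno_table(matrix(1L, 1, 1), indiv = "x", pop = "A", loci = "L1")
  expect_error(assign_individuals(gt, pan), "at least two")
})

test_that("success is non-increasing in the stringency threshold", {
  sim <- simulate_panel(sim_config(n_breeds = 4, n_loci = 150,
                                   breed_fst = 0.05, seed = 32))
  g <- glance(assign_individuals(sim$gt, sim$panel))
  expect_true(all(diff(g$success_pct) <= 0))
})

test_that("locus order does not change assignment results", {
  sim <- simulate_panel(sim_config(n_breeds = 3, n_loci = 60, seed = 33))
  loci <- panel_loci(sim$panel)
  a <- assign_individuals(sim$gt, sim$panel, loci = loci)
  b <- assign_individuals(sim$gt, sim$panel, loci = rev(loci))
  expect_equal(a$result, b$result, tolerance = 1e-12)
})

test_that("each fixed locus contributes ~10 units of LLR", {
  J <- 4
  pan <- freq_panel(matrix(rep(c(1, 0), J), 2, J, byrow = FALSE),
                    pop = c("A", "B"), n = 10, loci = paste0("L", 1:J))
  gt <- geno_table(matrix(2L, 1, J), indiv = "x", pop = "A",
                   loci = paste0("L", 1:J))
  for (j in seq_len(J)) {
    fit <- assign_individuals(gt, pan, loci = paste0("L", seq_len(j)))
    expect_equal(fit$result$llr, 10 * j, tolerance = 1e-3)
  }
})

test_that("pooling merges frequencies by allele counts", {
  pan <- freq_panel(matrix(c(0.2, 0.6, 0.5, 0.5), 2, 2),
                    pop = c("A", "B"), n = c(10, 30),
                    loci = c("L1", "L2"))
  pan3 <- freq_panel(rbind(as.matrix(pan[, c("L1", "L2")]), c(0.9, 0.1)),
                     pop = c("A", "B", "C"), n = c(10, 30, 5),
                     loci = c("L1", "L2"))
  merged <- pool_populations(pan3, pops = c("A", "B"))$panel
  expect_equal(merged[[ "L1" ]][merged$pop == "A+B"],
               (2 * 10 * 0.2 + 2 * 30 * 0.6) / (2 * 40))
  expect_equal(merged$n[merged$pop == "A+B"], 40)

  # identical frequencies and equal n: unchanged
  same <- freq_panel(matrix(c(0.3, 0.3, 0.8, 0.8), 2, 2),
                     pop = c("A", "B"), n = c(10, 10), loci = c("L1", "L2"))
  same3 <- freq_panel(rbind(as.matrix(same[, c("L1", "L2")]), c(0.5, 0.5)),
                      pop = c("A", "B", "C"), n = c(10, 10, 5),
                      loci = c("L1", "L2"))
  m2 <- pool_populations(same3, pops = c("A", "B"))$panel
  expect_equal(unlist(m2[m2$pop == "A+B", c("L1", "L2")], use.names = FALSE),
               c(0.3, 0.8))

  expect_error(pool_populations(pan, pops = c("A", "B")), "cannot pool all")
  expect_error(pool_populations(pan, pops = c("A", "Z")), "unknown population")
})

test_that("pooling near-identical breeds raises their own-assignment count", {
  succ <- vapply(c(301, 302, 303), function(seed) {
    sim <- related_sim(seed)
    r <- wright_fst(sim$panel, "pairwise")
    loci <- r$locus[1:100]
    fit <- assign_individuals(sim$gt, sim$panel, loci = loci)
    before <- sum(fit$result$correct_0[fit$result$true_pop %in% c("B5", "B6")])
    pooled <- pool_populations(sim$panel, sim$gt, pops = c("B5", "B6"))
    fit2 <- assign_individuals(pooled$gt, pooled$panel, loci = loci)
    after <- sum(fit2$result$correct_0[fit2$result$true_pop == "B5+B6"])
    after - before
  }, numeric(1))
  expect_true(all(succ >= 0))
})

test_that("error rates agree with direct counts and with overall success", {
  sim <- simulate_panel(sim_config(n_breeds = 4, n_loci = 100,
                                   breed_fst = 0.03, sample_sizes = 15,
                                   seed = 34))
  fit <- assign_individuals(sim$gt, sim$panel)
  er <- error_rates(fit, threshold = 0)
  d <- tidy(fit) |> dplyr::filter(threshold == 0)
  for (b in unique(d$true_pop)) {
    own <- d[d$true_pop == b, ]
    expect_equal(er$type_I[er$pop == b], mean(own$assigned != b))
  }
  overall <- glance(fit)$success_pct[glance(fit)$threshold == 0] / 100
  expect_equal(overall, 1 - sum(er$type_I * er$n_own) / sum(er$n_own))

  # perfect assignment: all zeros
  pan <- freq_panel(matrix(c(1, 0), 2, 1), pop = c("A", "B"), n = 10,
                    loci = "L1")
  gt <- geno_table(matrix(c(2L, 0L), 2, 1), indiv = c("x", "y"),
                   pop = c("A", "B"), loci = "L1")
  er0 <- error_rates(assign_individuals(gt, pan), threshold = 0)
  expect_equal(er0$type_I, c(0, 0))
  expect_equal(er0$type_II, c(0, 0))
})
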