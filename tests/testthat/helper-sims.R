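# Shared simulated cohorts, built once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- builder()
  .sim_cache[[key]]
}

# Standard cohort: 8 equally diverged breeds, the configuration used for the
# estimator-recovery and curve experiments.
std_sim <- function() {
  cached("std", function() {
    simulate_panel(sim_config(n_breeds = 8, n_loci = 5000, breed_fst = 0.10,
                              sample_sizes = 30, seed = 42))
  })
}

# One strongly diverged breed among seven weakly diverged ones: the setting
# in which global-FST ranking favours loci private to the outlier breed.
outlier_sim <- function() {
  cached("outlier", function() {
    simulate_panel(sim_config(n_breeds = 8, n_loci = 2000,
                              breed_fst = c(0.4, rep(0.05, 7)),
                              sample_sizes = 30, seed = 43))
  })
}

# Small cohort with a recently split breed pair (B5/B6) and unequal sizes.
related_sim <- function(seed) {
  simulate_panel(sim_config(n_breeds = 6, n_loci = 1500, breed_fst = 0.10,
                            sample_sizes = c(48, 30, 25, 20, 15, 12),
                            related_pairs = list(c(5, 6)), related_fst = 0.01,
                            seed = seed))
}

# Tiny deterministic panel/genotypes for unit examples.
toy_panel <- function() {
  freq_panel(matrix(c(0.2, 0.8,
                      0.5, 0.5,
                      0.9, 0.1), 2, 3),
             pop = c("A", "B"), n = c(10, 10), loci = c("L1", "L2", "L3"))
}

# --- independent oracles -----------------------------------------------------

# Weir-Cockerham FST, per-locus scalar loop coded directly from the
# variance-components definitions (kept deliberately separate from the
# vectorised implementation it checks).
wc_oracle_locus <- function(p, n) {
  r <- length(p)
  nbar <- sum(n)
  pw <- sum(n * p) / nbar
  msp <- sum(n * (p - pw)^2) / (r - 1)
  msg <- sum(n * p * (1 - p)) / sum(n - 1)
  nc <- (nbar - sum(n^2) / nbar) / (r - 1)
  den <- msp + (nc - 1) * msg
  if (den == 0) return(0)
  (msp - msg) / den
}

# Brute-force multilocus likelihood: per-genotype product of Hardy-Weinberg
# probabilities, computed genotype by genotype with scalar arithmetic.
loglik_oracle <- function(gt, panel, loci, zero = 1e-5, one = 0.99999) {
  pops <- panel$pop
  out <- matrix(0, nrow(gt), length(pops),
                dimnames = list(gt$indiv, pops))
  for (i in seq_len(nrow(gt))) {
    for (k in seq_along(pops)) {
      lik <- 1
      for (l in loci) {
        g <- gt[[l]][i]
        if (is.na(g)) next
        p <- panel[[l]][k]
        if (p <= 0) p <- zero
        if (p >= 1) p <- one
        lik <- lik * switch(as.character(g),
                            "2" = p^2, "1" = 2 * p * (1 - p), "0" = (1 - p)^2)
      }
      out[i, k] <- log10(lik)
    }
  }
  out
}
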