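#' Configure a multi-breed SNP simulation
#'
#' Describes a Balding-Nichols simulation of `n_breeds` diverged populations
#' genotyped at `n_loci` independent biallelic SNPs. Each locus draws an
#' ancestral reference-allele frequency uniformly from `ancestral_maf_range`
#' (assigned at random to either allele, so the spectrum is symmetric), then
#' each breed's frequency from a Beta with mean equal to the ancestral
#' frequency and divergence parameter `breed_fst[i]` (the F of the F-model:
#' the expected fixation index of that breed against the ancestral pool).
#' Breeds listed in `related_pairs` are instead drawn as a two-level
#' hierarchy: a shared pair-ancestor frequency at the breed-level F, then the
#' two members around it at `related_fst` — emulating recently split,
#' near-indistinguishable breed pairs.
#'
#' `min_maf_filter` mimics chip ascertainment: loci whose pooled sample MAF
#' falls below the threshold are discarded and redrawn until `n_loci` pass.
#'
#' @param n_breeds number of breeds K (>= 2).
#' @param n_loci number of loci L retained after the MAF filter.
#' @param breed_fst per-breed divergence F in (0, 1); recycled to length K.
#' @param sample_sizes per-breed diploid sample sizes (>= 2); recycled.
#' @param ancestral_maf_range interval within (0, 0.5] for the ancestral
#'   minor-allele frequency.
#' @param min_maf_filter pooled-MAF ascertainment threshold in `[0, 0.5)`.
#' @param related_pairs list of length-2 integer vectors of breed indices
#'   simulated from a shared recently-split source.
#' @param related_fst within-pair divergence for related pairs.
#' @param missing_rate per-call missing-completely-at-random probability.
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_breeds = 8, n_loci = 5000, breed_fst = 0.10,
                       sample_sizes = 30, ancestral_maf_range = c(0.05, 0.5),
                       min_maf_filter = 0.05, related_pairs = list(),
                       related_fst = 0.01, missing_rate = 0, seed = 1) {
  cfg <- list(
    n_breeds = as.integer(n_breeds), n_loci = as.integer(n_loci),
    breed_fst = rep_len(breed_fst, n_breeds),
    sample_sizes = rep_len(as.integer(sample_sizes), n_breeds),
    ancestral_maf_range = ancestral_maf_range,
    min_maf_filter = min_maf_filter,
    related_pairs = related_pairs, related_fst = related_fst,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  if (cfg$n_breeds < 2) abort("need at least 2 breeds")
  if (cfg$n_loci < 1) abort("need at least 1 locus")
  if (any(cfg$breed_fst <= 0 | cfg$breed_fst >= 1)) {
    abort("all breed_fst must lie in (0, 1)")
  }
  if (any(cfg$sample_sizes < 2)) abort("sample sizes must be >= 2")
  r <- cfg$ancestral_maf_range
  if (length(r) != 2 || r[1] <= 0 || r[2] > 0.5 || r[1] > r[2]) {
    abort("ancestral_maf_range must be an interval within (0, 0.5]")
  }
  if (min_maf_filter < 0 || min_maf_filter >= 0.5) {
    abort("min_maf_filter must lie in [0, 0.5)")
  }
  if (min_maf_filter >= r[2]) {
    abort("min_maf_filter must be below the upper end of ancestral_maf_range")
  }
  for (pr in cfg$related_pairs) {
    if (length(pr) != 2 || any(pr < 1 | pr > cfg$n_breeds) || pr[1] == pr[2]) {
      abort("each related pair must be two distinct breed indices")
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> K =", x$n_breeds, " L =", x$n_loci,
      " F =", paste(format(unique(x$breed_fst)), collapse = "/"),
      " N =", paste(unique(x$sample_sizes), collapse = "/"),
      " min MAF =", x$min_maf_filter, " seed =", x$seed, "\n")
  invisible(x)
}

# Balding-Nichols draw: breed frequency around ancestral p at divergence F.
rbn <- function(k, p, f) {
  rbeta(k, p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

# Deterministic per-attempt substream: locus attempt t always sees the same
# seed, so enlarging n_loci never perturbs earlier loci.
attempt_seed <- function(seed, t) {
  (as.numeric(seed) + 48271 * t) %% 2147483647
}

#' Simulate a frequency panel and matching genotypes
#'
#' Draws breed allele frequencies and individual genotypes under the model
#' described in [sim_config()]. Genotypes are Binomial(2, p) reference-allele
#' dosages; the returned panel holds the SAMPLE frequencies recomputed from
#' the emitted genotypes, so `sample_frequencies(gt)` reproduces it exactly
#' and downstream estimators see the same sampling noise a real panel would.
#'
#' @param cfg a [sim_config()].
#' @param max_attempts bound on total locus draws before the MAF filter is
#'   declared unsatisfiable.
#' @return A list with elements `panel` (a [freq_panel()]) and `gt`
#'   (a [geno_table()]); breeds are labelled `B1..BK`, loci `L00001..`.
#' @examples
#' sim <- simulate_panel(sim_config(n_breeds = 3, n_loci = 50, seed = 7))
#' sim$panel
#' @export
simulate_panel <- function(cfg, max_attempts = 200L * cfg$n_loci + 10000L) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$n_breeds
  L <- cfg$n_loci
  N <- cfg$sample_sizes
  pops <- paste0("B", seq_len(K))
  indiv <- unlist(lapply(seq_len(K), function(i) {
    sprintf("%s_i%02d", pops[i], seq_len(N[i]))
  }))
  true_pop <- rep(pops, N)
  n_ind <- sum(N)

  # membership in a related pair: the pair-ancestor uses the mean member F
  pair_of <- integer(K)
  for (idx in seq_along(cfg$related_pairs)) {
    pair_of[cfg$related_pairs[[idx]]] <- idx
  }

  dosage <- matrix(NA_integer_, n_ind, L)
  kept <- 0L
  t <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  while (kept < L) {
    t <- t + 1L
    if (t > max_attempts) {
      abort(paste0("MAF filter ", cfg$min_maf_filter, " not satisfiable: ",
                   t - 1L, " draws yielded only ", kept, " passing loci"))
    }
    set.seed(attempt_seed(cfg$seed, t))
    p_anc <- runif(1, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
    if (runif(1) < 0.5) p_anc <- 1 - p_anc

    pfreq <- numeric(K)
    pair_anc <- vapply(seq_along(cfg$related_pairs), function(idx) {
      members <- cfg$related_pairs[[idx]]
      rbn(1, p_anc, mean(cfg$breed_fst[members]))
    }, numeric(1))
    for (i in seq_len(K)) {
      pfreq[i] <- if (pair_of[i] > 0) {
        rbn(1, pair_anc[pair_of[i]], cfg$related_fst)
      } else {
        rbn(1, p_anc, cfg$breed_fst[i])
      }
    }

    g <- rep(NA_integer_, n_ind)
    for (i in seq_len(K)) {
      g[true_pop == pops[i]] <- rbinom(N[i], 2L, pfreq[i])
    }
    if (cfg$missing_rate > 0) {
      g[runif(n_ind) < cfg$missing_rate] <- NA_integer_
    }
    calls_per_pop <- tapply(!is.na(g), true_pop, sum)
    if (any(calls_per_pop == 0)) next
    pooled <- sum(g, na.rm = TRUE) / (2 * sum(!is.na(g)))
    if (min(pooled, 1 - pooled) < cfg$min_maf_filter) next
    kept <- kept + 1L
    dosage[, kept] <- g
  }

  loci <- sprintf("L%05d", seq_len(L))
  gt <- geno_table(dosage, indiv = indiv, pop = true_pop, loci = loci)
  list(panel = sample_frequencies(gt), gt = gt)
}
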