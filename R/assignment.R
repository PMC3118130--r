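#' Configure likelihood-based assignment
#'
#' Assignment follows the frequency-based likelihood method: an individual's
#' multilocus genotype likelihood in each reference population is the product
#' of Hardy-Weinberg genotype probabilities at independent loci, computed
#' from the population's observed allele frequencies. Because `log(0)` is
#' undefined, observed frequencies of 0 and 1 are clamped to
#' `zero_replacement` and `one_replacement` immediately before likelihood
#' computation (the panel itself keeps raw frequencies).
#'
#' Stringency is expressed on the base-10 log-likelihood ratio between the
#' individual's population of origin and the best alternative: thresholds
#' `0, 1, 2, 3` demand the genotype be 1, 10, 100 or 1000 times more likely
#' in the origin than in any other population.
#'
#' @param zero_replacement frequency substituted for an observed 0.
#' @param one_replacement frequency substituted for an observed 1.
#' @param thresholds non-decreasing LLR stringency levels.
#' @return A list of class `"assignment_config"`; the log base is fixed at 10.
#' @export
assignment_config <- function(zero_replacement = 1e-5,
                              one_replacement = 0.99999,
                              thresholds = c(0, 1, 2, 3)) {
  if (!(zero_replacement > 0 && zero_replacement < one_replacement &&
        one_replacement < 1)) {
    abort("need 0 < zero_replacement < one_replacement < 1")
  }
  if (is.unsorted(thresholds)) abort("thresholds must be non-decreasing")
  structure(list(zero_replacement = zero_replacement,
                 one_replacement = one_replacement,
                 thresholds = thresholds, log_base = 10),
            class = "assignment_config")
}

clamp_freq <- function(p, config) {
  p[p <= 0] <- config$zero_replacement
  p[p >= 1] <- config$one_replacement
  p
}

#' Multilocus genotype log-likelihoods
#'
#' For each individual and reference population, sums over non-missing loci
#' the base-10 log of the Hardy-Weinberg genotype probability: `p^2` for
#' reference homozygotes (dosage 2), `2p(1-p)` for heterozygotes and
#' `(1-p)^2` for alternate homozygotes, with `p` the clamped reference-allele
#' frequency in that population. Missing genotypes contribute a factor of 1
#' (log 0), so likelihoods remain comparable only across populations within
#' one individual.
#'
#' @param gt a genotype table of query individuals.
#' @param panel a frequency panel of reference populations.
#' @param loci ordered subset of loci to use; default all panel loci.
#' @param config an [assignment_config()].
#' @return A numeric matrix, individuals x populations, of log10 likelihoods.
#' @export
genotype_loglik <- function(gt, panel, loci = NULL, config = assignment_config()) {
  gt <- as_geno_table(gt)
  panel <- as_freq_panel(panel)
  loci <- loci %||% panel_loci(panel)
  if (!length(loci)) abort("empty locus subset")
  check_same_loci(loci, panel_loci(panel), "the frequency panel")
  check_same_loci(loci, panel_loci(gt), "the genotype table")

  loglik_matrix(gt_matrix(gt, loci), fp_matrix(panel, loci), config)
}

# matrix-level core: g indiv x loci dosages, p pops x loci raw frequencies
loglik_matrix <- function(g, p, config) {
  p <- clamp_freq(p, config)
  l2 <- 2 * log10(p)
  l1 <- log10(2 * p * (1 - p))
  l0 <- 2 * log10(1 - p)
  i2 <- (!is.na(g) & g == 2L) + 0
  i1 <- (!is.na(g) & g == 1L) + 0
  i0 <- (!is.na(g) & g == 0L) + 0
  ll <- i2 %*% t(l2) + i1 %*% t(l1) + i0 %*% t(l0)
  dimnames(ll) <- list(rownames(g), rownames(p))
  ll
}

# Core assignment from a loglik matrix and true labels; ties in the argmax
# are broken by population identifier (lexicographic) and reported.
assign_from_loglik <- function(ll, true_pop, thresholds) {
  pops <- colnames(ll)
  ord <- withr::with_collate("C", order(pops, method = "radix"))
  ll_o <- ll[, ord, drop = FALSE]
  pops_o <- pops[ord]

  best_j <- max.col(ll_o, ties.method = "first")
  n_ties <- sum(apply(ll_o, 1, function(r) sum(r == max(r)) > 1))
  if (n_ties > 0) {
    inform(paste0(n_ties, " individuals with tied maximum log-likelihoods; ",
                  "ties broken by population identifier"))
  }
  best_pop <- pops_o[best_j]
  own <- ll[cbind(seq_len(nrow(ll)), match(true_pop, pops))]
  if (anyNA(own)) abort("true population absent from the reference panel")
  alt <- vapply(seq_len(nrow(ll)), function(i) {
    max(ll[i, pops != true_pop[i]])
  }, numeric(1))
  llr <- own - alt

  res <- tibble::tibble(indiv = rownames(ll), true_pop = true_pop,
                        best_pop = best_pop, loglik_true = own,
                        loglik_best_other = alt, llr = llr)
  for (t in thresholds) {
    ok <- llr > t
    res[[paste0("assigned_", t)]] <- ifelse(ok, true_pop, best_pop)
    res[[paste0("correct_", t)]] <- ok
  }
  res
}

#' Assign individuals to reference populations
#'
#' Computes per-individual log-likelihoods against every reference
#' population, the log-likelihood ratio (LLR) of the known origin against the
#' best non-origin population, and the awarded population at each stringency
#' threshold: an individual is correctly assigned at threshold `t` when
#' `LLR > t` (strictly); otherwise it is assigned to the population with the
#' highest overall log-likelihood.
#'
#' @inheritParams genotype_loglik
#' @return An object of class `"pop_assignment"`: a list with `result` (a
#'   tibble with per-individual `llr`, `best_pop` and `assigned_t` /
#'   `correct_t` columns per threshold), `loglik` (the individuals x
#'   populations matrix), `thresholds` and `n_loci`. [tidy()] gives one row
#'   per individual and threshold; [glance()] the overall success per
#'   threshold.
#' @examples
#' sim <- simulate_panel(sim_config(n_breeds = 3, n_loci = 100, seed = 2))
#' fit <- assign_individuals(sim$gt, sim$panel)
#' glance(fit)
#' @export
assign_individuals <- function(gt, panel, loci = NULL,
                               config = assignment_config()) {
  panel <- as_freq_panel(panel)
  if (nrow(panel) < 2) {
    abort("assignment needs at least two reference populations")
  }
  gt <- as_geno_table(gt)
  ll <- genotype_loglik(gt, panel, loci, config)
  res <- assign_from_loglik(ll, gt$pop, config$thresholds)
  structure(list(result = res, loglik = ll, thresholds = config$thresholds,
                 n_loci = length(loci %||% panel_loci(panel)),
                 config = config),
            class = "pop_assignment")
}

#' @export
print.pop_assignment <- function(x, ...) {
  cat("<pop_assignment> ", nrow(x$result), " individuals, ",
      ncol(x$loglik), " reference populations, ", x$n_loci, " loci\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname assign_individuals
#' @param x a `pop_assignment` object.
#' @param ... unused.
#' @method tidy pop_assignment
#' @export
tidy.pop_assignment <- function(x, ...) {
  res <- x$result
  purrr::map_dfr(x$thresholds, function(t) {
    tibble::tibble(indiv = res$indiv, true_pop = res$true_pop,
                   threshold = t, llr = res$llr,
                   assigned = res[[paste0("assigned_", t)]],
                   correct = res[[paste0("correct_", t)]])
  })
}

#' @rdname assign_individuals
#' @method glance pop_assignment
#' @export
glance.pop_assignment <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     success_pct = 100 * mean(.data$correct),
                     .groups = "drop")
}

#' Per-population success rates of an assignment
#'
#' @param x a `pop_assignment` object.
#' @return A tibble with columns `pop`, `threshold`, `n`, `n_correct`,
#'   `success_pct`.
#' @export
success_by_pop <- function(x) {
  stopifnot(inherits(x, "pop_assignment"))
  tidy(x) |>
    dplyr::group_by(pop = .data$true_pop, .data$threshold) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     success_pct = 100 * mean(.data$correct),
                     .groups = "drop")
}

#' Per-population type I and type II error rates
#'
#' At a given stringency threshold, a population's type I error (false
#' negatives for that population) is the fraction of its own individuals not
#' correctly assigned to it at that stringency (so overall success equals one
#' minus the size-weighted mean type I error), and its type II error (false
#' positives) is the fraction of
#' individuals awarded to it whose true origin is elsewhere; a population
#' receiving no assignments has type II error 0 by convention.
#'
#' @param x a `pop_assignment` object.
#' @param threshold one of the thresholds the assignment was computed at.
#' @return A tibble with columns `pop`, `n_own`, `type_I`, `n_assigned`,
#'   `type_II`.
#' @export
error_rates <- function(x, threshold = 0) {
  stopifnot(inherits(x, "pop_assignment"))
  if (!threshold %in% x$thresholds) {
    abort(paste0("assignment was not computed at threshold ", threshold))
  }
  d <- tidy(x) |> dplyr::filter(.data$threshold == !!threshold)
  pops <- sort(unique(c(d$true_pop, colnames(x$loglik))))
  purrr::map_dfr(pops, function(b) {
    own <- d[d$true_pop == b, ]
    got <- d[d$assigned == b, ]
    tibble::tibble(
      pop = b, n_own = nrow(own),
      type_I = if (nrow(own)) mean(!own$correct) else 0,
      n_assigned = nrow(got),
      type_II = if (nrow(got)) mean(got$true_pop != b) else 0
    )
  })
}
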