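#' Rank loci by an informativeness score
#'
#' Orders loci by decreasing score with a deterministic tie rule: tied scores
#' are broken by locus identifier (C-locale lexicographic), so the ranking is
#' a total order reproducible across runs and platforms.
#'
#' @param scores a data frame with columns `locus` and `score` (a `method`
#'   column is carried through), or a named numeric vector.
#' @param method optional method label attached to the output.
#' @return A tibble of class `"marker_ranking"` with columns
#'   `rank`, `locus`, `score`, `method`, ordered by decreasing score.
#' @export
rank_markers <- function(scores, method = NULL) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble::tibble(locus = names(scores), score = unname(scores))
  }
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("locus", "score") %in% names(scores)))
  bad <- !is.finite(scores$score)
  if (any(bad)) {
    abort(paste0("non-finite scores at loci: ",
                 paste(head(scores$locus[bad], 5), collapse = ", ")))
  }
  method <- method %||% scores$method[1] %||% "score"
  ord <- withr::with_collate("C",
    order(-scores$score, scores$locus, method = "radix"))
  out <- tibble::tibble(rank = seq_len(nrow(scores)),
                        locus = scores$locus[ord],
                        score = scores$score[ord],
                        method = method)
  class(out) <- c("marker_ranking", class(out))
  out
}

score_panel <- function(panel, scores, method) {
  rank_markers(tibble::tibble(locus = panel_loci(panel),
                              score = unname(as.numeric(scores))),
               method = method)
}

pairs_of <- function(k) {
  if (k < 2) abort("need at least 2 populations")
  utils::combn(k, 2)
}

#' Delta: mean absolute allele-frequency difference
#'
#' For a biallelic locus and two populations, delta is the absolute
#' difference of reference-allele frequencies; with K > 2 populations the
#' value is averaged over all K(K-1)/2 unordered pairs. Scores lie in
#' `[0, 1]`, with 1 meaning fixation for opposite alleles in some pair.
#'
#' @param panel a [freq_panel()] with K >= 2 populations.
#' @return A `marker_ranking` tibble (see [rank_markers()]).
#' @examples
#' p <- freq_panel(matrix(c(0.2, 0.5, 0.8), 3, 1), pop = c("A", "B", "C"),
#'                 n = 10, loci = "L1")
#' delta_informativeness(p)  # mean(0.3, 0.6, 0.3) = 0.4
#' @export
delta_informativeness <- function(panel) {
  panel <- as_freq_panel(panel)
  p <- fp_matrix(panel)
  pr <- pairs_of(nrow(p))
  d <- abs(p[pr[1, ], , drop = FALSE] - p[pr[2, ], , drop = FALSE])
  score_panel(panel, colMeans(d), "delta")
}

# Wright's FST for a frequency matrix (rows = populations): var / p(1-p),
# with the population (divide-by-K) variance and the unweighted mean.
wright_stat <- function(p) {
  pbar <- colMeans(p)
  v <- colMeans(sweep(p, 2, pbar)^2)
  den <- pbar * (1 - pbar)
  ifelse(den == 0, 0, v / den)
}

#' Wright's fixation index as an informativeness score
#'
#' Per locus, `F_ST = var(p) / (pbar (1 - pbar))` where the variance of the
#' population allele frequencies is the population (divide-by-K) variance and
#' `pbar` their unweighted mean; the K = 2 fixation case then scores exactly
#' 1. `mode = "global"` computes one estimate over all K populations;
#' `mode = "pairwise"` averages the two-population estimates over all pairs.
#' A locus monomorphic across every population (the 0/0 case) scores 0.
#'
#' @inheritParams delta_informativeness
#' @param mode `"global"` or `"pairwise"`.
#' @return A `marker_ranking` tibble.
#' @export
wright_fst <- function(panel, mode = c("global", "pairwise")) {
  mode <- match.arg(mode)
  panel <- as_freq_panel(panel)
  p <- fp_matrix(panel)
  if (nrow(p) < 2) abort("need at least 2 populations")
  if (mode == "global") {
    s <- wright_stat(p)
  } else {
    pr <- pairs_of(nrow(p))
    acc <- matrix(0, ncol(pr), ncol(p))
    for (j in seq_len(ncol(pr))) {
      acc[j, ] <- wright_stat(p[pr[, j], , drop = FALSE])
    }
    s <- colMeans(acc)
  }
  score_panel(panel, s, paste0("wright_", mode))
}

# Weir & Cockerham's FST from sample allele frequencies and sample sizes,
# via the method-of-moments variance components (MSP/MSG formulation).
# p: populations x loci sample frequencies; n: per-population diploid sizes.
wc_stat <- function(p, n) {
  r <- nrow(p)
  nsum <- sum(n)
  pbar_w <- colSums(p * n) / nsum
  msp <- colSums(n * sweep(p, 2, pbar_w)^2) / (r - 1)
  msg <- colSums(n * p * (1 - p)) / sum(n - 1)
  nc <- (nsum - sum(n^2) / nsum) / (r - 1)
  den <- msp + (nc - 1) * msg
  out <- ifelse(den == 0, 0, (msp - msg) / den)
  attr(out, "degenerate") <- sum(den == 0)
  out
}

#' Weir & Cockerham's F_ST (variance-components estimator)
#'
#' The ANOVA-based moment estimator computed from sample allele frequencies
#' and per-population sample sizes, which corrects for unequal and finite
#' samples. Per locus, with r populations of diploid sizes `n_i` and sample
#' frequencies `p_i`:
#' `MSP = sum(n_i (p_i - pw)^2) / (r - 1)` (pw the size-weighted mean),
#' `MSG = sum(n_i p_i (1 - p_i)) / sum(n_i - 1)`,
#' `n_c = (sum(n_i) - sum(n_i^2)/sum(n_i)) / (r - 1)`, and
#' `F_ST = (MSP - MSG) / (MSP + (n_c - 1) MSG)`.
#' Negative estimates (within-population pairs less similar than
#' between-population pairs, i.e. no differentiation) are retained. A locus
#' with a zero denominator — monomorphic for the same allele in every
#' population — scores 0, with a warning reporting the count.
#'
#' @inheritParams wright_fst
#' @return A `marker_ranking` tibble; pairwise mode averages the
#'   two-population estimates over all pairs.
#' @export
wc_fst <- function(panel, mode = c("global", "pairwise")) {
  mode <- match.arg(mode)
  panel <- as_freq_panel(panel)
  p <- fp_matrix(panel)
  n <- panel$n
  if (nrow(p) < 2) abort("need at least 2 populations")
  if (any(n < 2)) abort("Weir-Cockerham estimator needs n >= 2 per population")
  degen <- 0L
  if (mode == "global") {
    s <- wc_stat(p, n)
    degen <- attr(s, "degenerate")
  } else {
    pr <- pairs_of(nrow(p))
    acc <- matrix(0, ncol(pr), ncol(p))
    for (j in seq_len(ncol(pr))) {
      ij <- pr[, j]
      sj <- wc_stat(p[ij, , drop = FALSE], n[ij])
      degen <- degen + attr(sj, "degenerate")
      acc[j, ] <- sj
    }
    s <- colMeans(acc)
  }
  if (degen > 0) {
    warn(paste0(degen, " degenerate (all-monomorphic) locus estimates set to 0"))
  }
  score_panel(panel, as.numeric(s), paste0("wc_", mode))
}

#' PCA squared-loading informativeness
#'
#' Performs principal component analysis on the population x locus frequency
#' matrix (each locus centred by its across-population mean, no scaling — the
#' Paschou-style allele-frequency PCA) and scores each locus by the sum of
#' its squared loadings over the *significant* components. Component rank k
#' is significant when its eigenvalue exceeds the `significance_rule`
#' quantile of rank-k eigenvalues from `n_random_matrices` randomized panels,
#' each built by resampling every locus's K frequency values with replacement
#' across populations (destroying between-population structure while keeping
#' each locus's marginal frequency spectrum).
#'
#' @inheritParams delta_informativeness
#' @param n_random_matrices randomized panels used for the significance null.
#' @param significance_rule quantile in (0, 1] of the null eigenvalues that a
#'   real eigenvalue must exceed; 1 demands exceeding the null maximum.
#' @param seed optional integer seed for the randomization (RNG state is
#'   restored afterwards).
#' @return A `marker_ranking` tibble with attribute `n_significant`, the
#'   number of significant components used.
#' @export
pca_informativeness <- function(panel, n_random_matrices = 100,
                                significance_rule = 0.95, seed = NULL) {
  panel <- as_freq_panel(panel)
  p <- fp_matrix(panel)
  K <- nrow(p)
  L <- ncol(p)
  if (K < 3) abort("PCA informativeness needs at least 3 populations")
  if (L < K) abort("PCA informativeness needs at least as many loci as populations")
  if (n_random_matrices < 1) abort("n_random_matrices must be >= 1")

  # canonical row/column order, so results do not depend on input ordering
  p_ord <- p[order(rownames(p)), , drop = FALSE]
  pc <- prcomp(p_ord, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  nk <- length(ev)

  p_null <- p_ord[, order(colnames(p_ord)), drop = FALSE]
  draw_null <- function() {
    idx <- matrix(sample.int(K, K * L, replace = TRUE), K, L)
    rnd <- matrix(p_null[cbind(as.vector(idx), rep(seq_len(L), each = K))], K, L)
    ev_r <- prcomp(rnd, center = TRUE, scale. = FALSE)$sdev^2
    length(ev_r) <- nk          # pad with NA if fewer components
    ev_r
  }
  run_null <- function() {
    vapply(seq_len(n_random_matrices), function(i) draw_null(), numeric(nk))
  }
  null_ev <- if (is.null(seed)) run_null() else withr::with_seed(seed, run_null())
  crit <- apply(null_ev, 1, quantile, probs = significance_rule, na.rm = TRUE)
  sig <- which(ev > crit)

  if (!length(sig)) {
    warn("no significant principal components; all PCA scores set to 0")
    scores <- rep(0, L)
  } else {
    v <- pc$rotation[, sig, drop = FALSE]
    scores <- rowSums(v^2)
  }
  out <- score_panel(panel, as.numeric(scores), "pca")
  attr(out, "n_significant") <- length(sig)
  out
}

#' Compare two marker rankings
#'
#' Quantifies agreement between two informativeness rankings of the same
#' locus set: the Spearman rank correlation of the score vectors (average
#' ranks for ties) and the size of the overlap between the two top-`top_n`
#' marker sets.
#'
#' @param r1,r2 `marker_ranking` tibbles over the same loci.
#' @param top_n size of the head of each ranking to intersect.
#' @return A tibble with columns `rho`, `overlap`, `top_n`,
#'   `method1`, `method2`.
#' @export
compare_rankings <- function(r1, r2, top_n = 500) {
  if (!setequal(r1$locus, r2$locus) || nrow(r1) != nrow(r2)) {
    abort("rankings cover different locus sets")
  }
  s2 <- r2$score[match(r1$locus, r2$locus)]
  rho <- cor(r1$score, s2, method = "spearman")
  top_n <- min(top_n, nrow(r1))
  overlap <- length(intersect(r1$locus[seq_len(top_n)],
                              r2$locus[seq_len(top_n)]))
  tibble::tibble(rho = rho, overlap = overlap, top_n = top_n,
                 method1 = r1$method[1], method2 = r2$method[1])
}
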