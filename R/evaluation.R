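#' Random-panel negative control
#'
#' Draws `n_sets` panels of `set_size` loci uniformly without replacement,
#' runs the cumulative assignment curve on each (loci in random draw order,
#' i.e. no informativeness ranking), and averages success across sets at each
#' grid point and threshold. Comparing the ranked-marker curve against this
#' mean curve shows the gain from informativeness ranking; the conventional
#' comparison is at the strictest stringency (LLR > 3).
#'
#' @inheritParams cumulative_assignment
#' @param n_sets number of random marker sets.
#' @param set_size loci per set (also the curve's `max_markers`).
#' @param seed optional seed for the draws, independent of any simulation
#'   stream; RNG state is restored afterwards.
#' @return A tibble of class `"assignment_curves"` (`pop = "overall"` only)
#'   with the across-set mean `success_pct` and attribute `per_set` holding
#'   the per-set curves.
#' @export
random_panel_control <- function(gt, panel, n_sets = 20, set_size = 400,
                                 step = 20, config = assignment_config(),
                                 seed = NULL) {
  panel <- as_freq_panel(panel)
  loci <- panel_loci(panel)
  if (set_size > length(loci)) {
    abort(paste0("set_size ", set_size, " exceeds available loci ",
                 length(loci)))
  }
  draws <- function() {
    purrr::map(seq_len(n_sets), function(s) sample(loci, set_size))
  }
  sets <- if (is.null(seed)) draws() else withr::with_seed(seed, draws())
  per_set <- purrr::map_dfr(seq_len(n_sets), function(s) {
    ranking <- tibble::tibble(locus = sets[[s]])
    cumulative_assignment(gt, panel, ranking, max_markers = set_size,
                          step = step, config = config) |>
      dplyr::filter(.data$pop == "overall") |>
      dplyr::mutate(set = s)
  })
  out <- per_set |>
    dplyr::group_by(.data$n_markers, .data$threshold) |>
    dplyr::summarise(pop = "overall", n = .data$n[1],
                     n_correct = mean(.data$n_correct),
                     success_pct = mean(.data$success_pct), .groups = "drop")
  class(out) <- c("assignment_curves", class(out))
  attr(out, "per_set") <- per_set
  out
}

ranking_fun <- function(method) {
  switch(method,
    delta = delta_informativeness,
    wright_global = function(p) wright_fst(p, "global"),
    wright_pairwise = function(p) wright_fst(p, "pairwise"),
    wc_global = function(p) wc_fst(p, "global"),
    wc_pairwise = function(p) wc_fst(p, "pairwise"),
    pca = pca_informativeness,
    abort(paste0("unknown ranking method `", method, "`"))
  )
}

#' Training/holdout cross-validation of assignment
#'
#' Estimates assignment power for individuals absent from the reference
#' panel. Per population, a holdout set is removed: all designated query
#' individuals when the population's reference size exceeds `size_cutoff`,
#' otherwise `holdout_small` randomly chosen queries. Reference allele
#' frequencies are re-estimated from the remaining (training) individuals,
#' markers are re-ranked on the training panel (avoiding selection leakage;
#' pass `ranking` to reuse a fixed ranking instead), and the holdouts are
#' assigned against the training panel along the cumulative grid.
#'
#' @param gt genotype table holding the full reference cohort.
#' @param method ranking method: one of `"delta"`, `"wright_global"`,
#'   `"wright_pairwise"`, `"wc_global"`, `"wc_pairwise"`, `"pca"`.
#' @param queries optional character vector of individuals eligible as
#'   holdouts; default all.
#' @param size_cutoff reference size above which all queries are held out.
#' @param holdout_small holdout count for populations at or below the cutoff.
#' @param ranking optional pre-computed `marker_ranking` to reuse instead of
#'   re-ranking on training frequencies.
#' @param seed optional seed for the holdout draws; RNG state restored.
#' @inheritParams cumulative_assignment
#' @return A list with `curves` (holdout `assignment_curves`), `holdout`
#'   (individual ids), `training_panel` and `ranking` (the training-derived
#'   ranking actually used).
#' @export
cross_validate <- function(gt, method = "wright_pairwise", queries = NULL,
                           size_cutoff = 50, holdout_small = 5,
                           max_markers = 400, step = 20,
                           config = assignment_config(), ranking = NULL,
                           seed = NULL) {
  gt <- as_geno_table(gt)
  queries <- queries %||% gt$indiv
  pick <- function() {
    unlist(lapply(split(gt$indiv, gt$pop), function(ids) {
      q <- intersect(ids, queries)
      if (length(ids) > size_cutoff) return(q)
      if (length(q) < holdout_small) {
        abort(paste0("population `", gt$pop[gt$indiv == ids[1]],
                     "` has only ", length(q), " query individuals; ",
                     holdout_small, " needed for the holdout"))
      }
      sample(q, holdout_small)
    }), use.names = FALSE)
  }
  holdout <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())

  train <- gt[!gt$indiv %in% holdout, , drop = FALSE]
  left <- table(train$pop)
  if (length(left) < length(unique(gt$pop)) || any(left < 2)) {
    short <- setdiff(unique(gt$pop), names(left)[left >= 2])
    abort(paste0("population `", short[1],
                 "` retains fewer than 2 training individuals"))
  }
  training_panel <- sample_frequencies(train)
  if (is.null(ranking)) ranking <- ranking_fun(method)(training_panel)
  test <- gt[gt$indiv %in% holdout, , drop = FALSE]
  curves <- cumulative_assignment(test, training_panel, ranking,
                                  max_markers = max_markers, step = step,
                                  config = config)
  list(curves = curves, holdout = holdout, training_panel = training_panel,
       ranking = ranking)
}

#' Mean pairwise differentiation per population
#'
#' For every unordered population pair, the pairwise informativeness score
#' (mean across all loci) is computed with the chosen estimator; each
#' population's differentiation is then the average over the pairs it belongs
#' to. This is the x-axis of the differentiation-versus-assignment-success
#' relationship.
#'
#' @param panel a frequency panel.
#' @param method `"wright"` (variance ratio) or `"wc"` (Weir-Cockerham).
#' @return A tibble with columns `pop` and `mean_fst`.
#' @export
breed_mean_fst <- function(panel, method = c("wright", "wc")) {
  method <- match.arg(method)
  panel <- as_freq_panel(panel)
  p <- fp_matrix(panel)
  K <- nrow(p)
  pr <- pairs_of(K)
  pair_mean <- vapply(seq_len(ncol(pr)), function(j) {
    ij <- pr[, j]
    s <- if (method == "wright") wright_stat(p[ij, , drop = FALSE])
         else wc_stat(p[ij, , drop = FALSE], panel$n[ij])
    mean(s)
  }, numeric(1))
  mean_fst <- vapply(seq_len(K), function(i) {
    mean(pair_mean[pr[1, ] == i | pr[2, ] == i])
  }, numeric(1))
  tibble::tibble(pop = panel$pop, mean_fst = mean_fst)
}

#' Correlation between breed differentiation and assignment success
#'
#' Spearman rank correlation (with two-sided p-value) between per-population
#' assignment success and per-population mean pairwise differentiation —
#' testing whether genetically distinct populations are easier to assign.
#'
#' @param success a data frame with columns `pop` and `success_pct` (e.g.
#'   [success_by_pop()] filtered to one grid point and threshold).
#' @param fst a data frame with columns `pop` and `mean_fst` (see
#'   [breed_mean_fst()]).
#' @return A tibble with columns `rho`, `p_value`, `n_pops`.
#' @export
differentiation_vs_success <- function(success, fst) {
  d <- dplyr::inner_join(tibble::as_tibble(success), tibble::as_tibble(fst),
                         by = "pop")
  if (nrow(d) < 3) abort("need at least 3 populations")
  if (var(d$success_pct) == 0 || var(d$mean_fst) == 0) {
    abort("constant vector: rank correlation undefined")
  }
  ct <- suppressWarnings(cor.test(d$success_pct, d$mean_fst,
                                  method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_pops = nrow(d))
}
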