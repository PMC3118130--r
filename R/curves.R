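#' Assignment success along a cumulative marker grid
#'
#' Evaluates assignment precision as markers are added in descending order of
#' informativeness: for `n = step, 2*step, ..., max_markers`, individuals are
#' assigned using the top-`n` loci of `ranking`, and overall plus
#' per-population success is recorded at every stringency threshold.
#' Log-likelihoods are accumulated incrementally across the grid, so the cost
#' is one pass over `max_markers` loci.
#'
#' @inheritParams genotype_loglik
#' @param ranking a `marker_ranking` (or any tibble with a `locus` column in
#'   rank order) covering at least `max_markers` loci.
#' @param max_markers largest panel size evaluated.
#' @param step grid increment (> 0).
#' @return A tibble of class `"assignment_curves"` with columns `n_markers`,
#'   `threshold`, `pop` (population label or `"overall"`), `n`, `n_correct`,
#'   `success_pct`.
#' @export
cumulative_assignment <- function(gt, panel, ranking, max_markers = 400,
                                  step = 20, config = assignment_config()) {
  if (step <= 0) abort("step must be positive")
  gt <- as_geno_table(gt)
  panel <- as_freq_panel(panel)
  if (nrow(panel) < 2) abort("need at least two reference populations")
  loci <- ranking$locus
  if (length(loci) < max_markers) {
    abort(paste0("ranking covers only ", length(loci), " loci; max_markers = ",
                 max_markers))
  }
  loci <- loci[seq_len(max_markers)]
  check_same_loci(loci, panel_loci(panel), "the frequency panel")
  check_same_loci(loci, panel_loci(gt), "the genotype table")
  g_all <- gt_matrix(gt, loci)
  p_all <- fp_matrix(panel, loci)
  grid <- seq(step, max_markers, by = step)
  ll <- NULL
  out <- purrr::map_dfr(seq_along(grid), function(gi) {
    lo <- if (gi == 1) 1 else grid[gi - 1] + 1
    sel <- lo:grid[gi]
    inc <- loglik_matrix(g_all[, sel, drop = FALSE],
                         p_all[, sel, drop = FALSE], config)
    ll <<- if (is.null(ll)) inc else ll + inc
    res <- assign_from_loglik(ll, gt$pop, config$thresholds)
    fake <- structure(list(result = res, loglik = ll,
                           thresholds = config$thresholds),
                      class = "pop_assignment")
    dplyr::bind_rows(
      glance(fake) |> dplyr::mutate(pop = "overall", .before = 1),
      success_by_pop(fake)
    ) |> dplyr::mutate(n_markers = grid[gi], .before = 1)
  })
  out <- out[, c("n_markers", "threshold", "pop", "n", "n_correct",
                 "success_pct")]
  class(out) <- c("assignment_curves", class(out))
  out
}

#' Fit the asymptotic success curve
#'
#' Fits the asymptotic regression model `y = a + b * exp(c * x)` to percent
#' success `y` against panel size `x` by nonlinear least squares
#' (Levenberg-Marquardt). With `a > 0`, `b < 0` and `c < 0` the curve is the
#' law of diminishing returns: `a` is the asymptotic success, `a + b` the
#' intercept at `x = 0` and `c` the log rate of approach to the asymptote.
#' Starting values are `a = max(y)`, `c = -0.01`, `b = y[1] - a`.
#'
#' @param points an `assignment_curves` tibble (then filtered to
#'   `pop == "overall"` at `threshold`), or any data frame with columns
#'   `n_markers` and `success_pct`; at least 4 points, not all equal.
#' @param threshold stringency level to extract when `points` is a full
#'   curve table.
#' @return An object of class `"curve_fit"` with elements `a`, `b`, `c`,
#'   `fit` (the underlying `nls` object) and `data`. [tidy()] returns the
#'   parameter table, [glance()] fit summaries; see [invert_curve()] for
#'   panel-size targets.
#' @export
fit_assignment_curve <- function(points, threshold = NULL) {
  d <- tibble::as_tibble(points)
  if ("pop" %in% names(d)) d <- d[d$pop == "overall", ]
  if ("threshold" %in% names(d)) {
    if (is.null(threshold)) {
      thr <- unique(d$threshold)
      if (length(thr) > 1) abort("several thresholds present; pick one")
      threshold <- thr
    }
    d <- d[d$threshold == threshold, ]
  }
  stopifnot(all(c("n_markers", "success_pct") %in% names(d)))
  d <- d[order(d$n_markers), c("n_markers", "success_pct")]
  if (nrow(d) < 4) abort("need at least 4 curve points")
  if (diff(range(d$success_pct)) == 0) {
    abort("constant success curve: asymptotic model is degenerate")
  }
  a0 <- max(d$success_pct)
  c0 <- -0.01
  b0 <- d$success_pct[1] - a0
  if (b0 == 0) b0 <- -1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      success_pct ~ a + b * exp(c * n_markers), data = d,
      start = list(a = a0, b = b0, c = c0),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 500)
    ),
    error = function(e) abort(paste0("curve fit failed to converge: ",
                                     conditionMessage(e)))
  )
  cf <- as.list(coef(fit))
  structure(list(a = cf$a, b = cf$b, c = cf$c, fit = fit, data = d,
                 threshold = threshold),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> y = %.4f + %.4f * exp(%.6f * x)\n", x$a, x$b, x$c))
  invisible(x)
}

#' @rdname fit_assignment_curve
#' @param x a `curve_fit` object.
#' @param ... unused.
#' @method tidy curve_fit
#' @export
tidy.curve_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @rdname fit_assignment_curve
#' @method glance curve_fit
#' @export
glance.curve_fit <- function(x, ...) {
  r <- stats::resid(x$fit)
  tibble::tibble(a = x$a, b = x$b, c = x$c, n = nrow(x$data),
                 sigma = summary(x$fit)$sigma, rss = sum(r^2),
                 diminishing_returns = x$a > 0 && x$b < 0 && x$c < 0)
}

#' Panel size needed to reach a target success level
#'
#' Inverts the fitted asymptotic curve: the panel size at which success
#' reaches `target_pct` is `x* = log((target - a) / b) / c`. The estimate is
#' generally fractional; the paper-style report is the smallest marker count
#' whose fitted success passes the target. When the asymptote `a` lies at or
#' below the target the target is unreachable and an error is raised.
#'
#' @param fit a `curve_fit`, or a list/vector with elements `a`, `b`, `c`.
#' @param target_pct target success level(s), same scale as the fitted `y`
#'   (percent).
#' @return Numeric vector of (fractional) marker counts.
#' @examples
#' invert_curve(list(a = 100, b = -60, c = -0.02), 95)  # ~124.25
#' @export
invert_curve <- function(fit, target_pct) {
  a <- fit$a %||% fit[["a"]]
  b <- fit$b %||% fit[["b"]]
  c <- fit$c %||% fit[["c"]]
  vapply(target_pct, function(y) {
    if (y >= a) {
      abort(paste0("asymptote below target: a = ", signif(a, 6),
                   " <= target ", y))
    }
    z <- (y - a) / b
    if (z <= 0) abort("target not reachable with these curve parameters")
    log(z) / c
  }, numeric(1))
}

#' @method autoplot assignment_curves
#' @export
autoplot.assignment_curves <- function(object, pops = "overall", ...) {
  d <- object[object$pop %in% pops, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_markers, y = .data$success_pct,
                                  colour = factor(.data$threshold))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~pop) +
    ggplot2::labs(x = "cumulative number of markers",
                  y = "correct assignment (%)",
                  colour = "LLR >") +
    ggplot2::theme_minimal()
}

#' @method autoplot marker_ranking
#' @export
autoplot.marker_ranking <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::labs(x = paste0("informativeness (", object$method[1], ")"),
                  y = "number of loci") +
    ggplot2::theme_minimal()
}
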