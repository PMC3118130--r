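#' Run the full marker-selection and assignment experiment
#'
#' One-call orchestration of the whole pipeline from a configuration list or
#' YAML file: simulate (or read) a reference panel and genotypes, rank
#' markers with each requested method, trace cumulative assignment curves,
#' fit the asymptotic model and invert it at the target success levels, and
#' run the random-panel control. All tables are written as TSV under
#' `out_dir` together with a run log recording the configuration and seed.
#'
#' Configuration keys (all optional unless noted):
#' \describe{
#'   \item{simulation}{list passed to [sim_config()]; mutually exclusive with
#'     `panel`/`genotypes` paths.}
#'   \item{panel, genotypes}{TSV paths of an existing panel and cohort.}
#'   \item{methods}{ranking methods (default `delta`, `wright_pairwise`,
#'     `wc_pairwise`, `pca`).}
#'   \item{max_markers, step}{cumulative grid (default 400 by 20).}
#'   \item{targets}{success levels to invert (default 90, 95, 98).}
#'   \item{random_control}{list with `n_sets`, `set_size` (default 20, 400);
#'     set to `FALSE` to skip.}
#'   \item{seed}{integer; drives simulation, PCA nulls and the control.}
#' }
#'
#' @param config a named list or path to a YAML file.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with `panel`, `gt`, `rankings`, `curves`,
#'   `fits`, `targets`, `random_control`.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  methods <- config$methods %||%
    c("delta", "wright_pairwise", "wc_pairwise", "pca")
  max_markers <- config$max_markers %||% 400
  step <- config$step %||% 20
  targets <- config$targets %||% c(90, 95, 98)
  acfg <- assignment_config()
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  logf("run_experiment seed=", seed, " methods=", paste(methods, collapse = ","))

  if (!is.null(config$panel)) {
    panel <- read_frequency_panel(config$panel)
    gt <- read_genotypes(config$genotypes)
    logf("inputs read: ", nrow(panel), " populations, ",
         length(panel_loci(panel)), " loci, ", nrow(gt), " individuals")
  } else {
    sim_args <- config$simulation %||% list()
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_panel(cfg)
    panel <- sim$panel
    gt <- sim$gt
    write_frequency_panel(panel, file.path(out_dir, "panel.tsv"))
    write_genotypes(gt, file.path(out_dir, "genotypes.tsv"))
    logf("simulated: K=", cfg$n_breeds, " L=", cfg$n_loci)
  }

  rankings <- purrr::map(setNames(methods, methods), function(m) {
    r <- if (m == "pca") {
      pca_informativeness(panel, seed = seed)
    } else {
      ranking_fun(m)(panel)
    }
    write_ranking(r, file.path(out_dir, paste0("ranking_", m, ".tsv")))
    r
  })

  curves <- purrr::imap(rankings, function(r, m) {
    cv <- cumulative_assignment(gt, panel, r, max_markers = max_markers,
                                step = step, config = acfg)
    write.table(cv, file.path(out_dir, paste0("curves_", m, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cv
  })

  fits <- purrr::map(curves, function(cv) {
    purrr::map(setNames(acfg$thresholds, paste0("llr", acfg$thresholds)),
               function(t) {
      tryCatch(fit_assignment_curve(cv, threshold = t),
               error = function(e) NULL)
    })
  })
  target_tbl <- purrr::imap_dfr(fits, function(ft, m) {
    purrr::imap_dfr(ft, function(f, tn) {
      if (is.null(f)) return(tibble::tibble())
      purrr::map_dfr(targets, function(y) {
        x <- tryCatch(invert_curve(f, y), error = function(e) NA_real_)
        tibble::tibble(method = m, threshold = tn, target_pct = y,
                       n_markers = x)
      })
    })
  })
  write.table(target_tbl, file.path(out_dir, "panel_size_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  rc <- NULL
  if (!isFALSE(config$random_control)) {
    rcc <- config$random_control %||% list()
    rc <- random_panel_control(gt, panel,
                               n_sets = rcc$n_sets %||% 20,
                               set_size = min(rcc$set_size %||% 400,
                                              length(panel_loci(panel))),
                               step = step, config = acfg,
                               seed = seed + 7919)
    write.table(rc, file.path(out_dir, "random_control.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  logf("done; outputs in ", out_dir)
  invisible(list(panel = panel, gt = gt, rankings = rankings, curves = curves,
                 fits = fits, targets = target_tbl, random_control = rc))
}
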