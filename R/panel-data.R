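#' Frequency panels and genotype tables
#'
#' The two tabular containers used throughout the package are plain tibbles
#' with a fixed leading-column layout, so they pipe through dplyr verbs and
#' round-trip losslessly through TSV:
#'
#' * A **frequency panel** holds reference-allele frequencies per population:
#'   columns `pop` (character), `n` (diploid sample size used to estimate the
#'   frequencies) and one numeric column in `[0, 1]` per locus.
#' * A **genotype table** holds individual diploid genotypes as reference
#'   allele dosage: columns `indiv`, `pop` (the individual's true population)
#'   and one integer column per locus with values in `{0, 1, 2, NA}`.
#'
#' `freq_panel()` and `geno_table()` build the containers from a matrix plus
#' identifiers; `as_freq_panel()` / `as_geno_table()` validate any data frame
#' with the right columns (e.g. one produced by dplyr manipulation or read
#' from disk) and reattach the class.
#'
#' @param freq numeric matrix, populations x loci, reference-allele
#'   frequencies in `[0, 1]`.
#' @param pop character vector of population identifiers (one per row).
#' @param n integer vector of per-population diploid sample sizes.
#' @param loci character vector of locus identifiers (one per column).
#' @return A tibble of subclass `"freq_panel"` or `"geno_table"`.
#' @examples
#' freq_panel(matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2), pop = c("A", "B"),
#'            n = c(10, 12), loci = c("L1", "L2"))
#' @export
freq_panel <- function(freq, pop, n, loci = colnames(freq)) {
  freq <- as.matrix(freq)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(freq)))
  stopifnot(length(pop) == nrow(freq), length(loci) == ncol(freq))
  n <- rep_len(as.integer(n), nrow(freq))
  colnames(freq) <- loci
  out <- tibble::tibble(pop = as.character(pop), n = n)
  out <- dplyr::bind_cols(out, tibble::as_tibble(freq))
  as_freq_panel(out)
}

#' @rdname freq_panel
#' @param dosage integer matrix, individuals x loci, values in `{0, 1, 2, NA}`.
#' @param indiv character vector of individual identifiers.
#' @export
geno_table <- function(dosage, indiv, pop, loci = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(dosage)))
  pop <- rep_len(as.character(pop), nrow(dosage))
  stopifnot(length(indiv) == nrow(dosage), length(loci) == ncol(dosage))
  storage.mode(dosage) <- "integer"
  colnames(dosage) <- loci
  out <- tibble::tibble(indiv = as.character(indiv), pop = as.character(pop))
  out <- dplyr::bind_cols(out, tibble::as_tibble(dosage))
  as_geno_table(out)
}

#' @rdname freq_panel
#' @param x a data frame with the documented column layout.
#' @export
as_freq_panel <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("pop", "n") %in% names(x)) ||
      !identical(names(x)[1:2], c("pop", "n"))) {
    abort("a frequency panel must start with columns `pop` and `n`")
  }
  if (anyDuplicated(x$pop)) abort("duplicate population identifiers")
  loci <- setdiff(names(x), c("pop", "n"))
  if (anyDuplicated(loci)) abort("duplicate locus identifiers")
  m <- as.matrix(x[, loci, drop = FALSE])
  if (!is.numeric(m)) {
    l <- loci[which(!vapply(x[loci], is.numeric, logical(1)))[1]]
    abort(paste0("locus column `", l, "` is not numeric"))
  }
  if (anyNA(m) || any(m < 0 | m > 1)) {
    bad <- which(is.na(m) | m < 0 | m > 1, arr.ind = TRUE)[1, ]
    v <- m[bad[1], bad[2]]
    if (is.na(v)) {
      abort(paste0("missing frequency at locus `", loci[bad[2]], "`"))
    }
    abort(paste0("frequency outside [0, 1] at locus `", loci[bad[2]],
                 "`, population `", x$pop[bad[1]], "` (", v, ")"))
  }
  if (any(x$n < 1)) abort("per-population sample size `n` must be >= 1")
  class(x) <- c("freq_panel", class(tibble::tibble()))
  x
}

#' @rdname freq_panel
#' @export
as_geno_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("indiv", "pop") %in% names(x)) ||
      !identical(names(x)[1:2], c("indiv", "pop"))) {
    abort("a genotype table must start with columns `indiv` and `pop`")
  }
  if (anyDuplicated(x$indiv)) abort("duplicate individual identifiers")
  loci <- setdiff(names(x), c("indiv", "pop"))
  if (length(loci)) {
    m <- as.matrix(x[, loci, drop = FALSE])
    if (!is.numeric(m)) {
      l <- loci[which(!vapply(x[loci], is.numeric, logical(1)))[1]]
      abort(paste0("locus column `", l, "` is not numeric"))
    }
    off <- !is.na(m) & !(m == 0L | m == 1L | m == 2L)
    if (any(off)) {
      bad <- which(off, arr.ind = TRUE)[1, ]
      abort(paste0("dosage outside {0, 1, 2, NA} at locus `", loci[bad[2]],
                   "`, individual `", x$indiv[bad[1]], "`"))
    }
  }
  class(x) <- c("geno_table", class(tibble::tibble()))
  x
}

#' Locus identifiers of a panel or genotype table
#' @param x a frequency panel or genotype table.
#' @return Character vector of locus identifiers, in column order.
#' @export
panel_loci <- function(x) {
  setdiff(names(x), c("pop", "n", "indiv"))
}

# internal matrix views -------------------------------------------------------

fp_matrix <- function(panel, loci = NULL) {
  loci <- loci %||% panel_loci(panel)
  m <- as.matrix(panel[, loci, drop = FALSE])
  rownames(m) <- panel$pop
  m
}

gt_matrix <- function(gt, loci = NULL) {
  loci <- loci %||% panel_loci(gt)
  m <- as.matrix(gt[, loci, drop = FALSE])
  rownames(m) <- gt$indiv
  m
}

check_same_loci <- function(a_loci, b_loci, where = "inputs") {
  missing <- setdiff(a_loci, b_loci)
  if (length(missing)) {
    abort(paste0(length(missing), " loci absent from ", where, " (first: `",
                 missing[1], "`)"))
  }
  invisible(TRUE)
}

#' Estimate population allele frequencies from genotypes
#'
#' Computes, for every population and locus, the sample frequency of the
#' reference allele: the dosage sum divided by twice the number of non-missing
#' calls. This is the panel re-estimation step used after pooling populations
#' and inside cross-validation.
#'
#' @param gt a genotype table (see [geno_table()]).
#' @return A [freq_panel()] with one row per population present in `gt`;
#'   `n` is the number of individuals per population.
#' @examples
#' gt <- geno_table(matrix(c(2L, 1L, 0L), 3, 1), indiv = c("a", "b", "c"),
#'                  pop = "P", loci = "L1")
#' sample_frequencies(gt)  # p = 0.5
#' @export
sample_frequencies <- function(gt) {
  gt <- as_geno_table(gt)
  loci <- panel_loci(gt)
  if (!length(loci)) abort("genotype table has no loci")
  g <- gt_matrix(gt)
  pops <- unique(gt$pop)
  freq <- matrix(NA_real_, length(pops), length(loci),
                 dimnames = list(pops, loci))
  n <- integer(length(pops))
  for (i in seq_along(pops)) {
    gi <- g[gt$pop == pops[i], , drop = FALSE]
    n[i] <- nrow(gi)
    calls <- colSums(!is.na(gi))
    if (any(calls == 0)) {
      j <- which(calls == 0)[1]
      abort(paste0("no non-missing calls for population `", pops[i],
                   "` at locus `", loci[j], "`"))
    }
    freq[i, ] <- colSums(gi, na.rm = TRUE) / (2 * calls)
  }
  freq_panel(freq, pop = pops, n = n, loci = loci)
}

#' Per-population mean minor-allele frequency
#'
#' The minor-allele frequency of a locus in a population is
#' `min(p, 1 - p)`; this averages it over all loci, per population. Low
#' per-breed MAF indicates reduced within-breed diversity at the assayed loci
#' (often an ascertainment artefact of chip design).
#'
#' @param x a frequency panel, or a genotype table (frequencies are then
#'   estimated with [sample_frequencies()] first).
#' @return A tibble with columns `pop` and `mean_maf`.
#' @export
per_breed_maf <- function(x) {
  if (inherits(x, "geno_table") || "indiv" %in% names(x)) {
    x <- sample_frequencies(x)
  }
  x <- as_freq_panel(x)
  p <- fp_matrix(x)
  tibble::tibble(pop = x$pop, mean_maf = unname(rowMeans(pmin(p, 1 - p))))
}

#' Pool populations into a single reference breed
#'
#' Merges two or more populations into one, as is done when reference
#' populations show no detectable differentiation (e.g. two sampling cohorts
#' of the same breed). When genotypes are supplied the merged population's
#' frequencies are re-estimated from the union of member genotypes; otherwise
#' they are the sample-size-weighted average of member frequencies (identical
#' when there are no missing calls).
#'
#' @param panel a frequency panel.
#' @param gt optional genotype table consistent with `panel`; its labels are
#'   rewritten too.
#' @param pops character vector (length >= 2) of populations to merge.
#' @param new_name label for the merged population; defaults to the member
#'   names joined with `"+"`.
#' @return A list with elements `panel` and `gt` (the latter `NULL` when no
#'   genotypes were given).
#' @export
pool_populations <- function(panel, gt = NULL, pops, new_name = NULL) {
  panel <- as_freq_panel(panel)
  if (length(pops) < 2) abort("need at least two populations to pool")
  missing <- setdiff(pops, panel$pop)
  if (length(missing)) abort(paste0("unknown population `", missing[1], "`"))
  if (length(setdiff(panel$pop, pops)) == 0) {
    abort("cannot pool all populations: at least one other must remain")
  }
  new_name <- new_name %||% paste(pops, collapse = "+")
  loci <- panel_loci(panel)

  if (!is.null(gt)) {
    gt <- as_geno_table(gt)
    check_same_loci(loci, panel_loci(gt), "genotype table")
    gt$pop[gt$pop %in% pops] <- new_name
    merged <- sample_frequencies(gt[gt$pop == new_name, , drop = FALSE])
    mfreq <- fp_matrix(merged, loci)
    mn <- merged$n[1]
  } else {
    sel <- panel$pop %in% pops
    w <- panel$n[sel]
    mfreq <- colSums(fp_matrix(panel, loci)[sel, , drop = FALSE] * w) / sum(w)
    mfreq <- matrix(mfreq, 1, dimnames = list(new_name, loci))
    mn <- sum(w)
  }

  keep <- !(panel$pop %in% pops)
  out <- freq_panel(rbind(fp_matrix(panel, loci)[keep, , drop = FALSE], mfreq),
                    pop = c(panel$pop[keep], new_name),
                    n = c(panel$n[keep], mn), loci = loci)
  list(panel = out, gt = gt)
}
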