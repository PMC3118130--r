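#' Read and write frequency panels and genotype tables
#'
#' TSV dialects (tab-separated, header row, no quoting):
#'
#' * Frequency panel: columns `pop`, `n`, then one column per locus holding
#'   the reference-allele frequency. One row per population.
#' * Genotype table: columns `indiv`, `pop`, then one column per locus
#'   holding reference-allele dosage `0/1/2`; missing calls are the literal
#'   `NA`. Empty cells are rejected rather than silently coerced.
#'
#' Readers validate every cell and report the offending line and column;
#' writers emit deterministic row and column order, so write-then-read is the
#' identity.
#'
#' @param path file path.
#' @return `read_frequency_panel()` a [freq_panel()];
#'   `read_genotypes()` a [geno_table()].
#' @name panel_io
NULL

read_tsv_strict <- function(path) {
  d <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                  check.names = FALSE, na.strings = NULL)
  if (anyDuplicated(names(d))) {
    abort(paste0("malformed header in ", path, ": duplicate column `",
                 names(d)[anyDuplicated(names(d))], "`"))
  }
  d
}

parse_numeric_cols <- function(d, cols, path, what, allow_na = FALSE) {
  for (col in cols) {
    v <- d[[col]]
    if (any(v == "")) {
      abort(paste0(path, " line ", which(v == "")[1] + 1,
                   ": empty cell in column `", col, "`"))
    }
    num <- suppressWarnings(as.numeric(ifelse(v == "NA", NA, v)))
    bad <- which(is.na(num) & v != "NA")
    if (length(bad)) {
      abort(paste0(path, " line ", bad[1] + 1, ": non-numeric value `",
                   v[bad[1]], "` in column `", col, "`"))
    }
    if (!allow_na && anyNA(num)) {
      abort(paste0(path, " line ", which(is.na(num))[1] + 1,
                   ": missing ", what, " in column `", col, "`"))
    }
    d[[col]] <- num
  }
  d
}

#' @rdname panel_io
#' @export
read_frequency_panel <- function(path) {
  d <- read_tsv_strict(path)
  if (length(names(d)) < 3 || !identical(names(d)[1:2], c("pop", "n"))) {
    abort(paste0("malformed header in ", path,
                 ": expected `pop`, `n`, then locus columns"))
  }
  loci <- names(d)[-(1:2)]
  d <- parse_numeric_cols(d, c("n", loci), path, "frequency")
  for (l in loci) {
    bad <- which(d[[l]] < 0 | d[[l]] > 1)
    if (length(bad)) {
      abort(paste0(path, " line ", bad[1] + 1, ": frequency ", d[[l]][bad[1]],
                   " outside [0, 1] in column `", l, "`"))
    }
  }
  as_freq_panel(tibble::as_tibble(d))
}

#' @rdname panel_io
#' @param panel a [freq_panel()].
#' @export
write_frequency_panel <- function(panel, path) {
  panel <- as_freq_panel(panel)
  write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @param gt a [geno_table()].
#' @export
write_genotypes <- function(gt, path) {
  gt <- as_geno_table(gt)
  write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @param format `"tsv"` or `"vcf"`. VCF input must be biallelic with a GT
#'   field; dosage counts the REF allele, `./.` and half-calls become
#'   missing, and multiallelic records are skipped with a warning.
#' @param pop_map for VCF input, a data frame with columns `indiv` and `pop`
#'   mapping every sample to its true population.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), pop_map = NULL) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path, pop_map))
  d <- read_tsv_strict(path)
  if (length(names(d)) < 3 || !identical(names(d)[1:2], c("indiv", "pop"))) {
    abort(paste0("malformed header in ", path,
                 ": expected `indiv`, `pop`, then locus columns"))
  }
  loci <- names(d)[-(1:2)]
  d <- parse_numeric_cols(d, loci, path, "dosage", allow_na = TRUE)
  for (l in loci) d[[l]] <- as.integer(d[[l]])
  as_geno_table(tibble::as_tibble(d))
}

read_genotypes_vcf <- function(path, pop_map) {
  if (is.null(pop_map)) {
    abort("VCF input needs a `pop_map` data frame (columns indiv, pop)")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warn(paste0(sum(multi), " multiallelic sites skipped"))
  }
  gtm <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
  ids <- fix[!multi, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[!multi, "CHROM"], ":",
                                         fix[!multi, "POS"])[is.na(ids) | ids == "."]
  samples <- colnames(gtm)
  unmapped <- setdiff(samples, pop_map$indiv)
  if (length(unmapped)) {
    abort(paste0("sample `", unmapped[1], "` missing from pop_map"))
  }
  dose_one <- function(g) {
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(al, function(a) {
      if (length(a) != 2 || any(a == ".")) return(NA_integer_)
      sum(a == "0")
    }, integer(1))
  }
  dosage <- t(apply(gtm, 1, dose_one))  # loci x samples
  dosage <- t(dosage)                   # samples x loci
  colnames(dosage) <- ids
  geno_table(dosage, indiv = samples,
             pop = pop_map$pop[match(samples, pop_map$indiv)], loci = ids)
}

#' @rdname panel_io
#' @param ranking a `marker_ranking`.
#' @export
write_ranking <- function(ranking, path) {
  write.table(ranking[, c("rank", "locus", "score", "method")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_ranking <- function(path) {
  d <- read_tsv_strict(path)
  d <- parse_numeric_cols(d, c("rank", "score"), path, "score")
  out <- tibble::as_tibble(d)
  out$rank <- as.integer(out$rank)
  class(out) <- c("marker_ranking", class(out))
  out
}
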