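#' SNP genotype panel
#'
#' The central genotype container: a sites table, an integer dosage matrix and
#' a samples table. Genotypes are stored on the diploid-coded scale used in
#' VCFs produced by joint calling: `0` = homozygous reference, `1` =
#' heterozygous, `2` = homozygous alternate, `NA` = missing. Haploid samples
#' (drones) are diploid-coded too, so a dosage of `1` in a haploid sample is a
#' heterozygous-drone artifact (see [handle_drone_heterozygotes()]).
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param geno Integer matrix, sites in rows, samples in columns, values in
#'   `{0, 1, 2, NA}`.
#' @param samples Tibble with columns `id`, `population`, `ploidy` (1 or 2).
#'
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(sites, geno, samples) {
  sites <- tibble::as_tibble(sites)
  samples <- tibble::as_tibble(samples)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    all(c("id", "population", "ploidy") %in% names(samples)),
    is.matrix(geno),
    nrow(geno) == nrow(sites),
    ncol(geno) == nrow(samples)
  )
  if (!all(samples$ploidy %in% c(1L, 2L))) {
    abort("sample ploidy must be 1 or 2")
  }
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) abort("genotype dosages must be 0, 1, 2 or NA")
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, ]
    geno <- geno[ord, , drop = FALSE]
  }
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    abort("duplicate site positions within a chromosome")
  }
  storage.mode(geno) <- "integer"
  colnames(geno) <- samples$id
  structure(
    list(sites = sites, geno = geno, samples = samples),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf(
    "<snp_matrix> %d sites x %d samples (%d haploid)\n",
    nrow(x$sites), nrow(x$samples), sum(x$samples$ploidy == 1L)
  ))
  pops <- table(x$samples$population)
  cat("populations:", paste(sprintf("%s=%d", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a SNP panel by sites and/or samples
#'
#' @param x A [snp_matrix()].
#' @param sites Logical or integer index over sites.
#' @param samples Logical or integer index over samples, or a character vector
#'   of sample ids or population labels.
#' @return A `snp_matrix`.
#' @export
snp_subset <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "snp_matrix"))
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  sj <- if (is.null(samples)) {
    seq_len(nrow(x$samples))
  } else if (is.character(samples)) {
    hit <- x$samples$id %in% samples | x$samples$population %in% samples
    if (!any(hit)) abort(paste0("no samples match: ", paste(samples, collapse = ", ")))
    which(hit)
  } else {
    samples
  }
  snp_matrix(x$sites[si, ], x$geno[si, sj, drop = FALSE], x$samples[sj, ])
}

#' Tidy a SNP panel into a long tibble
#'
#' One row per site x sample with the diploid-coded dosage.
#'
#' @param x A [snp_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `pos`, `id`, `population`, `ploidy`,
#'   `dosage`.
#' @export
tidy.snp_matrix <- function(x, ...) {
  long <- tibble::tibble(
    chrom = rep(x$sites$chrom, times = ncol(x$geno)),
    pos = rep(x$sites$pos, times = ncol(x$geno)),
    id = rep(x$samples$id, each = nrow(x$geno)),
    population = rep(x$samples$population, each = nrow(x$geno)),
    ploidy = rep(x$samples$ploidy, each = nrow(x$geno)),
    dosage = as.integer(x$geno)
  )
  long
}

#' Per-site allele counts within a set of samples
#'
#' Haploid samples contribute one allele copy (dosage/2), diploids two.
#' Heterozygous haploid calls are counted as one copy of each allele, but
#' should have been removed by [handle_drone_heterozygotes()] beforehand.
#'
#' @param x A [snp_matrix()].
#' @param samples Optional sample subset (as in [snp_subset()]).
#' @return Tibble with `chrom`, `pos`, `n_alleles` (called copies), `alt_count`
#'   and `alt_freq`.
#' @export
allele_counts <- function(x, samples = NULL) {
  if (!is.null(samples)) x <- snp_subset(x, samples = samples)
  g <- x$geno
  hap <- x$samples$ploidy == 1L
  called <- !is.na(g)
  copies <- matrix(rep(ifelse(hap, 1L, 2L), each = nrow(g)), nrow = nrow(g))
  alt <- g
  alt[, hap] <- alt[, hap, drop = FALSE] / 2 # 0/2 coding -> 0/1 copies; het=0.5 flagged upstream
  n_alleles <- rowSums(copies * called)
  alt_count <- rowSums(alt * called, na.rm = TRUE)
  tibble::tibble(
    chrom = x$sites$chrom,
    pos = x$sites$pos,
    n_alleles = as.integer(round(n_alleles)),
    alt_count = alt_count,
    alt_freq = ifelse(n_alleles > 0, alt_count / n_alleles, NA_real_)
  )
}

# internal: observed heterozygote indicator matrix (diploids only)
het_matrix <- function(x) {
  h <- x$geno == 1L
  h[, x$samples$ploidy == 1L] <- FALSE
  h
}
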