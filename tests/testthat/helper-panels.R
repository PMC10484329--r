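# Small reusable fixtures, all built in code.

small_config <- function(seed = 1L, ...) {
  args <- list(
    n_snps = 3000,
    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    n_selected_loci = 2,
    sample_sizes = c(lowland = 15, highland = 14, A = 19, C = 9, M = 85),
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(small_config())
    cache
  }
})

# hand-built tiny panel: 3 diploid samples in each of two populations
toy_matrix <- function(geno, pops = NULL, ploidy = NULL) {
  geno <- as.matrix(geno)
  ns <- ncol(geno)
  if (is.null(pops)) pops <- rep(c("p1", "p2"), each = ns / 2)
  if (is.null(ploidy)) ploidy <- rep(2L, ns)
  snp_matrix(
    sites = tibble::tibble(
      chrom = "chr1", pos = seq_len(nrow(geno)) * 1000L,
      ref = "A", alt = "G"
    ),
    geno = geno,
    samples = tibble::tibble(
      id = sprintf("s%02d", seq_len(ns)), population = pops,
      ploidy = as.integer(ploidy)
    )
  )
}
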