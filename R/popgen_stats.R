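#' Randomly pair haploid drones into pseudodiploid samples
#'
#' Haploid genotypes cannot enter diploid diversity estimators directly, so
#' drones are combined in random pairs: a pseudodiploid's dosage is the sum of
#' the two haploid alleles. An odd drone count drops one (logged). Pairing is
#' deterministic given the seed.
#'
#' @param mat A [snp_matrix()] whose haploid calls have been resolved by
#'   [handle_drone_heterozygotes()].
#' @param population Population label of the drones to pair.
#' @param seed Integer seed for the pairing permutation.
#' @return List: `matrix` (drones replaced by pseudodiploids; other samples
#'   untouched), `pairs` (tibble: pseudo_id, drone_1, drone_2), `dropped`
#'   (character, possibly empty).
#' @export
pair_haploids <- function(mat, population = "M", seed = 1L) {
  drones <- which(mat$samples$population == population & mat$samples$ploidy == 1L)
  if (length(drones) < 2) abort("need at least two drones to pair")
  g_dr <- mat$geno[, drones, drop = FALSE]
  if (any(g_dr == 1L, na.rm = TRUE)) {
    warn("haploid samples still carry heterozygous calls; run handle_drone_heterozygotes() first")
  }
  set.seed(seed)
  perm <- sample(drones)
  n_pair <- length(perm) %/% 2
  dropped <- if (length(perm) %% 2 == 1) mat$samples$id[perm[length(perm)]] else character(0)
  i1 <- perm[seq_len(n_pair) * 2 - 1]
  i2 <- perm[seq_len(n_pair) * 2]
  # 0/2-coded haploid dosages -> allele copies, summed
  pseudo <- mat$geno[, i1, drop = FALSE] / 2 + mat$geno[, i2, drop = FALSE] / 2
  storage.mode(pseudo) <- "integer"
  pairs <- tibble::tibble(
    pseudo_id = sprintf("pseudo_%02d", seq_len(n_pair)),
    drone_1 = mat$samples$id[i1], drone_2 = mat$samples$id[i2]
  )
  keep <- setdiff(seq_len(ncol(mat$geno)), drones)
  geno <- cbind(mat$geno[, keep, drop = FALSE], pseudo)
  samples <- dplyr::bind_rows(
    mat$samples[keep, ],
    tibble::tibble(id = pairs$pseudo_id, population = population, ploidy = 2L)
  )
  list(matrix = snp_matrix(mat$sites, geno, samples), pairs = pairs, dropped = dropped)
}

make_windows <- function(pos, window_bp, len = NULL) {
  if (is.null(len)) len <- max(pos)
  starts <- seq(1, len, by = window_bp)
  tibble::tibble(start = starts, end = pmin(starts + window_bp - 1, len))
}

#' Windowed nucleotide diversity (pi)
#'
#' Per-site `pi = 2 p (1-p) n/(n-1)` with `n` the called allele copies at the
#' site, summed over SNPs in each window and divided by the window length in
#' bp. The genome value is the unweighted mean over windows that contain at
#' least one called SNP.
#'
#' @param mat A [snp_matrix()].
#' @param population Optional population label to subset to.
#' @param window_bp Window size (default 50 kbp).
#' @param chrom_lengths Optional named vector; windows tile each chromosome
#'   from position 1 to its length (default: to the last SNP).
#' @return A tibble of class `pi_windows` (`chrom`, `start`, `end`, `n_snps`,
#'   `pi`), with the genome mean in `attr(, "genome_pi")` (also via
#'   [glance()]).
#' @export
nucleotide_diversity_windows <- function(mat, population = NULL,
                                         window_bp = 50000,
                                         chrom_lengths = NULL) {
  if (!is.null(population)) mat <- snp_subset(mat, samples = population)
  ac <- allele_counts(mat)
  p <- ac$alt_freq
  n <- ac$n_alleles
  pi_site <- ifelse(!is.na(p) & n > 1, 2 * p * (1 - p) * n / (n - 1), NA_real_)

  out <- purrr::map(unique(mat$sites$chrom), function(chr) {
    on_chr <- mat$sites$chrom == chr
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chr]] else NULL
    win <- make_windows(mat$sites$pos[on_chr], window_bp, len)
    idx <- findInterval(mat$sites$pos[on_chr], win$start)
    ps <- pi_site[on_chr]
    called <- !is.na(ps)
    win$n_snps <- as.integer(tabulate(idx[called], nbins = nrow(win)))
    sums <- rep(0, nrow(win))
    agg <- tapply(ps[called], idx[called], sum)
    sums[as.integer(names(agg))] <- agg
    win$pi <- sums / (win$end - win$start + 1)
    dplyr::mutate(win, chrom = chr, .before = 1)
  }) |> purrr::list_rbind()

  genome_pi <- mean(out$pi[out$n_snps > 0])
  structure(out, genome_pi = genome_pi, class = c("pi_windows", class(out)))
}

#' @export
glance.pi_windows <- function(x, ...) {
  tibble::tibble(
    genome_pi = attr(x, "genome_pi"),
    n_windows = sum(x$n_snps > 0),
    n_snps = sum(x$n_snps)
  )
}

#' Watterson's theta per bp
#'
#' `theta_W = S / (a_n * L)` with `S` the number of segregating sites in the
#' (sub)panel, `a_n` the harmonic number over `n - 1` and `n` the number of
#' sampled chromosomes (allele copies: 2 per diploid, 1 per haploid sample).
#'
#' @param mat A [snp_matrix()].
#' @param total_bp Sequence length the SNPs were ascertained over.
#' @param population Optional population subset.
#' @return Tibble: `S`, `n_chromosomes`, `a_n`, `theta_w` (per bp).
#' @export
watterson_theta <- function(mat, total_bp, population = NULL) {
  if (!is.null(population)) mat <- snp_subset(mat, samples = population)
  n_chr <- sum(ifelse(mat$samples$ploidy == 1L, 1L, 2L))
  if (n_chr < 2) abort("need at least two sampled chromosomes")
  ac <- allele_counts(mat)
  seg <- !is.na(ac$alt_freq) & ac$alt_count > 0 & ac$alt_count < ac$n_alleles
  S <- sum(seg)
  a_n <- sum(1 / seq_len(n_chr - 1))
  tibble::tibble(S = S, n_chromosomes = n_chr, a_n = a_n,
                 theta_w = S / (a_n * total_bp))
}

# per-population per-site summaries used by the FST estimators
pop_site_summary <- function(mat, population) {
  sub <- snp_subset(mat, samples = population)
  hap <- sub$samples$ploidy == 1L
  g <- sub$geno
  called <- !is.na(g)
  n_ind <- rowSums(called)
  ac <- allele_counts(sub)
  h_obs <- if (all(hap)) rep(0, nrow(g)) else {
    het <- g == 1L & !matrix(hap, nrow(g), ncol(g), byrow = TRUE)
    het[!called] <- FALSE
    dipcalled <- called & !matrix(hap, nrow(g), ncol(g), byrow = TRUE)
    nd <- rowSums(dipcalled)
    ifelse(nd > 0, rowSums(het) / nd, 0)
  }
  list(
    n_ind = n_ind, m_alleles = ac$n_alleles, p = ac$alt_freq,
    h = h_obs, any_haploid = any(hap)
  )
}

#' Per-SNP Weir-Cockerham FST variance components
#'
#' Two-population Weir & Cockerham (1984) estimator. For two all-diploid
#' populations the full a/b/c decomposition with observed heterozygosity is
#' used; if either population carries haploid samples, the haploid
#' (allele-count) form is used, with drones contributing single allele copies
#' and zero heterozygosity. Sites with fewer than two called genotypes in
#' either population get NA components. The ratio is NA when the denominator
#' is zero (monomorphic across both populations); negative per-SNP values are
#' retained.
#'
#' @param mat A [snp_matrix()].
#' @param pop_a,pop_b Population labels.
#' @return Tibble: `chrom`, `pos`, `num` (a), `den` (a+b+c), `fst`.
#' @export
wc_fst_per_snp <- function(mat, pop_a, pop_b) {
  if (!all(c(pop_a, pop_b) %in% mat$samples$population)) {
    abort("population absent from matrix")
  }
  s1 <- pop_site_summary(mat, pop_a)
  s2 <- pop_site_summary(mat, pop_b)

  if (s1$any_haploid || s2$any_haploid) {
    comp <- wc_components_haploid(s1$m_alleles, s1$p, s2$m_alleles, s2$p)
  } else {
    comp <- wc_components_diploid(s1$n_ind, s1$p, s1$h, s2$n_ind, s2$p, s2$h)
  }
  usable <- s1$n_ind >= 2 & s2$n_ind >= 2
  comp$num[!usable] <- NA_real_
  comp$den[!usable] <- NA_real_
  tibble::tibble(
    chrom = mat$sites$chrom, pos = mat$sites$pos,
    num = comp$num, den = comp$den,
    fst = ifelse(!is.na(comp$den) & comp$den != 0, comp$num / comp$den, NA_real_)
  )
}

# Weir & Cockerham (1984), r = 2 populations, diploid with observed het
wc_components_diploid <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nsum <- n1 + n2
  nc <- (nsum - (n1^2 + n2^2) / nsum) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / nsum
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(num = a, den = a + b + cc)
}

# haploid (allele-count) analogue: mean-squares form on m allele copies
wc_components_haploid <- function(m1, p1, m2, p2) {
  r <- 2
  msum <- m1 + m2
  pbar <- ifelse(msum > 0, (m1 * p1 + m2 * p2) / msum, NA_real_)
  MSP <- (m1 * (p1 - pbar)^2 + m2 * (p2 - pbar)^2) / (r - 1)
  MSG <- (m1 * p1 * (1 - p1) + m2 * p2 * (1 - p2)) / (msum - r)
  nc <- (msum - (m1^2 + m2^2) / msum) / (r - 1)
  a <- (MSP - MSG) / nc
  list(num = a, den = a + MSG)
}

#' Windowed Weir-Cockerham FST (ratio of sums)
#'
#' Windows tile each chromosome from position 1; the window value is the sum
#' of per-SNP numerators over the sum of denominators (the "weighted" FST of
#' the windowed scan). Empty windows carry `n_snps = 0` and NA value.
#'
#' @param per_snp Output of [wc_fst_per_snp()].
#' @param window_bp Window size (default 10 kbp).
#' @param chrom_lengths Optional named lengths for full tiling.
#' @return Tibble of class `fst_windows`: `chrom`, `start`, `end`, `n_snps`,
#'   `num`, `den`, `fst`.
#' @export
wc_fst_windowed <- function(per_snp, window_bp = 10000, chrom_lengths = NULL) {
  ok <- !is.na(per_snp$num) & !is.na(per_snp$den)
  out <- purrr::map(unique(per_snp$chrom), function(chr) {
    on_chr <- per_snp$chrom == chr
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[chr]] else NULL
    win <- make_windows(per_snp$pos[on_chr], window_bp, len)
    idx <- findInterval(per_snp$pos[on_chr], win$start)
    use <- ok[on_chr]
    win$n_snps <- as.integer(tabulate(idx[use], nbins = nrow(win)))
    agg_sum <- function(x) {
      s <- rep(0, nrow(win))
      a <- tapply(x[use], idx[use], sum)
      s[as.integer(names(a))] <- a
      s
    }
    win$num <- agg_sum(per_snp$num[on_chr])
    win$den <- agg_sum(per_snp$den[on_chr])
    dplyr::mutate(win, chrom = chr, .before = 1)
  }) |> purrr::list_rbind()
  out$fst <- ifelse(out$den > 0, out$num / out$den, NA_real_)
  structure(out, class = c("fst_windows", class(out)))
}

#' Genome-wide FST as a multi-locus ratio of sums (Reynolds-type)
#'
#' The coancestry estimator of Reynolds, Weir & Cockerham (1983): per-locus
#' variance components summed across all SNPs before taking the ratio
#' (identical components to the two-population Weir-Cockerham decomposition).
#'
#' @param mat A [snp_matrix()].
#' @param pop_a,pop_b Population labels.
#' @return Scalar FST estimate.
#' @export
reynolds_fst_genomewide <- function(mat, pop_a, pop_b) {
  per_snp <- wc_fst_per_snp(mat, pop_a, pop_b)
  ok <- !is.na(per_snp$num) & !is.na(per_snp$den)
  den <- sum(per_snp$den[ok])
  if (den == 0) abort("zero genome-wide FST denominator")
  sum(per_snp$num[ok]) / den
}

#' KING-robust pairwise kinship
#'
#' `phi = (N_het,het - 2 N_opposite_hom) / (N_het(i) + N_het(j))`, with all
#' counts over sites called in both samples. A sample against itself gives
#' 0.5. Pairs exceeding the relatedness threshold are flagged.
#'
#' @param mat A [snp_matrix()]; only diploid samples are used.
#' @param pairs Optional tibble (`sample_i`, `sample_j`); default all
#'   unordered pairs of diploid samples.
#' @param threshold Kinship level above which a pair is flagged
#'   (default 0.044, the lowest level indicating any degree of relatedness).
#' @param min_sites Minimum shared called sites for a defined estimate.
#' @return Tibble of [KinshipPair] records: `sample_i`, `sample_j`, `phi`,
#'   `n_shared_sites`, `flagged`.
#' @export
king_kinship <- function(mat, pairs = NULL, threshold = 0.044, min_sites = 50) {
  dip <- mat$samples$id[mat$samples$ploidy == 2L]
  sub <- snp_subset(mat, samples = which(mat$samples$ploidy == 2L))
  g <- sub$geno
  called <- !is.na(g)
  H <- (g == 1L) & called
  A0 <- (g == 0L) & called
  A2 <- (g == 2L) & called
  storage.mode(H) <- "numeric"
  storage.mode(A0) <- "numeric"
  storage.mode(A2) <- "numeric"
  storage.mode(called) <- "numeric"

  hh <- crossprod(H)                       # both het
  opp <- crossprod(A0, A2) + crossprod(A2, A0) # opposite homozygotes
  het_i <- crossprod(H, called)            # het in i, called in j
  shared <- crossprod(called)

  if (is.null(pairs)) {
    idx <- which(upper.tri(hh), arr.ind = TRUE)
    pairs <- tibble::tibble(sample_i = dip[idx[, 1]], sample_j = dip[idx[, 2]])
  }
  i <- match(pairs$sample_i, dip)
  j <- match(pairs$sample_j, dip)
  if (anyNA(i) || anyNA(j)) abort("pair references a non-diploid or unknown sample")
  ij <- cbind(i, j)
  ji <- cbind(j, i)
  denom <- het_i[ij] + het_i[ji]
  phi <- ifelse(denom > 0, (hh[ij] - 2 * opp[ij]) / denom, NA_real_)
  n_shared <- shared[ij]
  phi[n_shared < min_sites] <- NA_real_
  tibble::tibble(
    sample_i = pairs$sample_i, sample_j = pairs$sample_j,
    phi = phi, n_shared_sites = as.integer(n_shared),
    flagged = !is.na(phi) & phi > threshold
  )
}
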