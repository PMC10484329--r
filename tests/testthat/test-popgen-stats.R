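test_that("drone pairing is deterministic and yields homozygous pseudodiploids", {
  g <- matrix(rep(c(0L, 2L), each = 8), 4, 4, byrow = TRUE)
  mat <- toy_matrix(g, pops = rep("M", 4), ploidy = rep(1L, 4))
  p1 <- pair_haploids(mat, "M", seed = 3L)
  p2 <- pair_haploids(mat, "M", seed = 3L)
  expect_identical(p1$pairs, p2$pairs)
  expect_equal(nrow(p1$pairs), 2)
  expect_length(p1$dropped, 0)

  # identical haploids pair to a fully homozygous pseudodiploid
  expect_true(all(p1$matrix$geno %in% c(0L, 2L)))

  # 85 drones: 42 pairs, one dropped and logged
  sim <- small_sim()
  dr <- handle_drone_heterozygotes(sim$matrix)
  paired <- pair_haploids(dr$matrix, "M", seed = 1L)
  expect_equal(nrow(paired$pairs), 42)
  expect_length(paired$dropped, 1)
  expect_equal(sum(paired$matrix$samples$population == "M"), 42)
  expect_error(pair_haploids(toy_matrix(matrix(0L, 2, 2)), "p1"), "drones")
})

test_that("windowed nucleotide diversity matches hand evaluation", {
  # monomorphic panel
  mono <- toy_matrix(matrix(0L, 5, 4))
  pw <- nucleotide_diversity_windows(mono, window_bp = 10000)
  expect_true(all(pw$pi == 0))

  # one SNP at p = 0.5 with n = 2 chromosomes in a 10-kbp window:
  # pi = 2 * 0.5 * 0.5 * 2/1 / 10000 = 1e-4
  one <- toy_matrix(matrix(c(0L, 2L), 1, 2), pops = c("p1", "p1"),
                    ploidy = c(1L, 1L))
  pw1 <- nucleotide_diversity_windows(one, window_bp = 10000,
                                      chrom_lengths = c(chr1 = 10000))
  expect_equal(pw1$pi, 1e-4)
  expect_equal(attr(pw1, "genome_pi"), 1e-4)

  # generated panel: per-lineage pi near its closed-form expectation and in
  # the observed empirical order A > admixed > M > C
  sim <- small_sim()
  cfg <- small_config()
  pis <- purrr::map_dbl(
    setNames(nm = c("A", "C", "M", "lowland")),
    function(p) glance(nucleotide_diversity_windows(
      sim$matrix, population = p, chrom_lengths = cfg$chrom_lengths
    ))$genome_pi
  )
  expect_lt(abs(pis[["A"]] - expected_pi(cfg, "A")) / expected_pi(cfg, "A"), 0.1)
  expect_true(pis[["A"]] > pis[["lowland"]])
  expect_true(pis[["lowland"]] > pis[["M"]])
  expect_true(pis[["M"]] > pis[["C"]])

  # invariance under sample relabeling
  relabeled <- sim$matrix
  relabeled$samples$population[relabeled$samples$population %in%
                                 c("lowland", "highland")] <- "colombia"
  expect_equal(
    glance(nucleotide_diversity_windows(
      snp_subset(sim$matrix, samples = which(sim$matrix$samples$population %in%
                                               c("lowland", "highland")))))$genome_pi,
    glance(nucleotide_diversity_windows(relabeled, population = "colombia"))$genome_pi
  )
})

test_that("Watterson's theta follows S / (a_n L) and recovers simulations", {
  # S = 0
  expect_equal(watterson_theta(toy_matrix(matrix(0L, 3, 4)), 1000)$theta_w, 0)

  # S = 11, n = 4 chromosomes, L = 1000: 11 / (1.8333 * 1000)
  g <- matrix(0L, 11, 4)
  g[, 1] <- 2L
  mat <- toy_matrix(g, pops = rep("p1", 4), ploidy = c(1L, 1L, 1L, 1L))
  th <- watterson_theta(mat, 1000)
  expect_equal(th$n_chromosomes, 4)
  expect_equal(th$theta_w, 11 / (sum(1 / 1:3) * 1000), tolerance = 1e-12)
  expect_equal(th$theta_w, 0.006, tolerance = 1e-3)

  # coalescent recovery: Poisson mutations on simulated genealogies at
  # theta = 0.0047/bp over 906-bp loci, 10 haploid samples
  set.seed(42)
  theta_bp <- 0.0047; L <- 906; n_loci <- 150
  model <- split_model(n1 = 5, n2 = 5, t_split = 0, n_loci = n_loci, seed = 42L)
  geno <- list(); pos0 <- 0L
  s_per_locus <- numeric(n_loci)
  for (i in seq_len(n_loci)) {
    gen <- simulate_genealogy(model)
    n_mut <- rpois(1, scale_theta(L, theta_bp) * sum(gen$branches$length))
    s_per_locus[i] <- n_mut
    if (n_mut == 0) next
    hits <- sample.int(nrow(gen$branches), n_mut, replace = TRUE,
                       prob = gen$branches$length)
    # derived counts suffice: build haploid dosages per mutation
    for (h in hits) {
      d <- gen$branches$d1[h] + gen$branches$d2[h]
      row <- c(rep(2L, d), rep(0L, 10 - d))[sample.int(10)]
      geno[[length(geno) + 1]] <- row
    }
  }
  gmat <- do.call(rbind, geno)
  mat2 <- snp_matrix(
    tibble::tibble(chrom = "chr1", pos = seq_len(nrow(gmat)) * 10L,
                   ref = "A", alt = "G"),
    gmat,
    tibble::tibble(id = sprintf("h%02d", 1:10), population = "sim",
                   ploidy = rep(1L, 10))
  )
  est <- watterson_theta(mat2, total_bp = L * n_loci)
  se <- sd(s_per_locus / (sum(1 / 1:9) * L)) / sqrt(n_loci)
  expect_lt(abs(est$theta_w - theta_bp), 3 * se)
  expect_error(watterson_theta(snp_subset(mat2, samples = 1), 100), "two")
})

test_that("per-SNP Weir-Cockerham components match a brute-force transcription", {
  # fixed difference: FST = 1
  fixed <- toy_matrix(cbind(matrix(0L, 3, 10), matrix(2L, 3, 10)))
  expect_equal(wc_fst_per_snp(fixed, "p1", "p2")$fst, rep(1, 3))

  # identical frequencies and heterozygosity: no differentiation
  same <- toy_matrix(matrix(rep(c(0L, 1L, 2L), 4), 2, 12, byrow = TRUE))
  res_same <- wc_fst_per_snp(same, "p1", "p2")
  expect_true(all(res_same$num <= 0))
  expect_true(all(res_same$fst <= 0))

  # random toy panels against the independent genotype-by-genotype oracle
  set.seed(7)
  for (rep in 1:25) {
    g <- matrix(sample(c(0L, 1L, 2L, NA), 36, replace = TRUE,
                       prob = c(.4, .3, .25, .05)), 6, 6)
    mat <- toy_matrix(g)
    got <- wc_fst_per_snp(mat, "p1", "p2")
    for (i in 1:6) {
      want <- oracle_wc_fst_site(g[i, 1:3], g[i, 4:6])
      expect_equal(got$num[i], unname(want["a"]), tolerance = 1e-12)
      expect_equal(got$den[i], unname(want["d"]), tolerance = 1e-12)
    }
    expect_error(wc_fst_per_snp(mat, "p1", "nope"), "absent")
  }
})

test_that("windowed FST is the ratio of sums over member SNPs", {
  per <- tibble::tibble(
    chrom = "chr1", pos = c(500L, 10500L, 12500L, 30500L),
    num = c(0.2, 0.1, 0.3, -0.05), den = c(0.4, 0.5, 0.5, 0.2)
  )
  per$fst <- per$num / per$den
  win <- wc_fst_windowed(per, window_bp = 10000)
  expect_equal(win$fst[1], 0.5)                      # single-SNP window
  expect_equal(win$fst[2], (0.1 + 0.3) / (0.5 + 0.5)) # equal denominators: mean of ratios
  expect_equal(win$fst[2], mean(per$fst[2:3]))
  expect_equal(win$n_snps[3], 0)                     # empty window, undefined
  expect_true(is.na(win$fst[3]))
  expect_equal(sum(win$n_snps), 4)                   # tiling covers every SNP once
  expect_equal(win$start, c(1, 10001, 20001, 30001))
})

test_that("genome-wide ratio-of-sums FST is calibrated on the split model", {
  # identical populations: estimate near zero
  set.seed(5)
  p <- runif(400, 0.1, 0.9)
  g <- matrix(rbinom(400 * 30, 2, p), 400, 30)
  same <- toy_matrix(g, pops = rep(c("p1", "p2"), 15))
  expect_lt(abs(reynolds_fst_genomewide(same, "p1", "p2")), 0.02)

  # fixed differences at every site
  fixed <- toy_matrix(cbind(matrix(0L, 5, 6), matrix(2L, 5, 6)))
  expect_equal(reynolds_fst_genomewide(fixed, "p1", "p2"), 1)

  # split model at t = 0.0301 (4N units) reproduces FST = 1 - exp(-2t) = 0.058
  null <- simulate_snp_panel(split_model(t_split = fst_to_T(0.0584),
                                         n_loci = 60000, seed = 8L))
  expect_equal(null$weighted_fst, 0.0584, tolerance = 0.05)
})

test_that("KING-robust kinship separates self, parent-offspring and unrelated", {
  set.seed(11)
  n <- 3000
  p <- runif(n, 0.2, 0.8)
  parent1 <- rbinom(n, 2, p); parent2 <- rbinom(n, 2, p)
  transmit <- function(g) rbinom(n, 1, g / 2)
  child <- transmit(parent1) + transmit(parent2)
  unrelated <- rbinom(n, 2, p)
  mat <- toy_matrix(cbind(parent1, parent2, child, unrelated),
                    pops = rep("p1", 4))
  pairs <- tibble::tibble(
    sample_i = c("s01", "s01", "s01", "s02"),
    sample_j = c("s01", "s03", "s04", "s04")
  )
  kin <- king_kinship(mat, pairs, threshold = 0.044)
  expect_equal(kin$phi[1], 0.5)                       # self
  expect_equal(kin$phi[2], 0.25, tolerance = 0.1)     # parent-offspring
  expect_lt(abs(kin$phi[3]), 3 * 0.5 / sqrt(n))       # unrelated
  expect_true(kin$flagged[2])
  expect_false(kin$flagged[3])

  # unrelated simulated individuals within one population: mean phi ~ 0
  sim <- small_sim()
  col <- snp_subset(sim$matrix, samples = "lowland")
  kin2 <- king_kinship(col)
  expect_lt(abs(mean(kin2$phi)), 0.02)
})
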