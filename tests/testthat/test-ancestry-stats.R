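post_row <- function(pCC = 0, pCM = 0, pCA = 0, pMM = 0, pMA = 0, pAA = 0) {
  tibble::tibble(pCC = pCC, pCM = pCM, pCA = pCA, pMM = pMM, pMA = pMA, pAA = pAA)
}

test_that("diplotype posteriors reduce to per-lineage probabilities", {
  expect_equal(combine_posterior_A(post_row(pAA = 1))$pA, 1)
  expect_equal(combine_posterior_A(post_row(pMA = 1))$pA, 0.5)
  r <- combine_posterior_A(post_row(pAA = 0.5, pCA = 0.2, pMA = 0.1, pMM = 0.2))
  expect_equal(r$pA, 0.65)
  # the three lineage probabilities partition the mass
  expect_equal(r$pA + r$pC + r$pM, 1)
  many <- combine_posterior_A(dplyr::bind_rows(
    post_row(pCM = 0.4, pMM = 0.6), post_row(pCC = 1), post_row(pCA = 1)
  ))
  expect_true(all(abs(many$pA + many$pC + many$pM - 1) < 1e-9))
  expect_error(combine_posterior_A(post_row(pAA = 0.8)), "sum to 1")
})

test_that("the population ancestry track recovers the configured contrast", {
  # identical posteriors for everyone: delta = 0 everywhere
  base <- tidyr::crossing(
    snp_id = c("s1", "s2"), sample = c("a1", "a2", "b1", "b2")
  ) |>
    dplyr::mutate(
      chrom = "chr1", pos = rep(c(100L, 100L, 200L, 200L), 2)[1:8],
      population = rep(c("lowland", "highland"), 4)[1:8]
    ) |>
    dplyr::bind_cols(post_row(pAA = 1)[rep(1, 8), ])
  tr0 <- population_ancestry_track(base)
  expect_true(all(tr0$delta == 0))
  expect_error(population_ancestry_track(dplyr::filter(base, population == "lowland")),
               "population")

  # noiseless posteriors on a seeded panel: genome-mean delta matches the
  # 0.847 - 0.686 design contrast within simulation error
  cfg <- small_config(n_snps = 2000, n_selected_loci = 0, posterior_noise = 0)
  g <- generate_admixed_genotypes(generate_lineage_frequencies(cfg), cfg)
  pc <- generate_posteriors_and_clines(g$truth, cfg)
  tr <- population_ancestry_track(combine_posterior_A(pc$posteriors))
  target <- cfg$admix_A_lowland - cfg$admix_A_highland
  se <- sqrt(0.847 * 0.153 / (2 * 15) + 0.686 * 0.314 / (2 * 14)) / sqrt(2000)
  expect_lt(abs(mean(tr$delta) - target), 3 * se)

  # selection targets stand far above the genome-average delta
  cfg2 <- small_config(n_snps = 2000, posterior_noise = 0)
  g2 <- generate_admixed_genotypes(generate_lineage_frequencies(cfg2), cfg2)
  pc2 <- generate_posteriors_and_clines(g2$truth, cfg2)
  tr2 <- population_ancestry_track(combine_posterior_A(pc2$posteriors))
  sel_ids <- paste0(g2$truth$selected_snps$chrom, ":", g2$truth$selected_snps$pos)
  sel <- tr2$snp_id %in% sel_ids
  expect_gt(mean(tr2$delta[sel]), mean(tr2$delta[!sel]) + 0.3)
})

test_that("FST-ancestry and cline correlations behave under null and signal", {
  # perfectly concordant ordering: rho = 1
  win <- structure(
    tibble::tibble(chrom = "chr1", start = seq(1, 40001, 10000),
                   end = seq(10000, 50000, 10000), n_snps = 5L,
                   num = 1:5, den = 5, fst = (1:5) / 5),
    class = c("fst_windows", "tbl_df", "tbl", "data.frame")
  )
  tr <- tibble::tibble(chrom = "chr1", pos = seq(5000, 45000, 10000),
                       snp_id = paste0("s", 1:5), delta = (1:5) / 10)
  expect_equal(correlate_fst_ancestry(win, tr)$rho, 1)

  # independent tracks: |rho| below the 3/sqrt(n) null band
  set.seed(3)
  k <- 400
  win2 <- structure(
    tibble::tibble(chrom = "chr1", start = seq(1, by = 10000, length.out = k),
                   end = seq(10000, by = 10000, length.out = k),
                   n_snps = 5L, num = 1, den = 1, fst = runif(k)),
    class = c("fst_windows", "tbl_df", "tbl", "data.frame")
  )
  tr2 <- tibble::tibble(chrom = "chr1",
                        pos = seq(5000, by = 10000, length.out = k),
                        snp_id = paste0("s", 1:k), delta = runif(k))
  expect_lt(abs(correlate_fst_ancestry(win2, tr2)$rho), 3 / sqrt(k))
  expect_error(correlate_fst_ancestry(win2[1:2, ], tr2[1:2, ]), "3 paired")

  # cline correlation: exact when steepness is proportional to delta
  cl <- tibble::tibble(snp_id = tr2$snp_id, steepness = 2 * tr2$delta + 1)
  expect_equal(correlate_clines(tr2, cl)$r, 1)
  # permuted steepness kills it
  clp <- tibble::tibble(snp_id = tr2$snp_id,
                        steepness = sample(cl$steepness))
  expect_lt(abs(correlate_clines(tr2, clp)$r), 3 / sqrt(k))
  expect_error(correlate_clines(tr2, tibble::tibble(snp_id = "zz", steepness = 1)),
               "shared")

  # generator calibration: configured cline correlation is recovered
  cfg <- small_config(n_snps = 30000, chrom_lengths = c(chr1 = 6e6),
                      cline_correlation = 0.1, posterior_noise = 0,
                      n_selected_loci = 3,
                      sample_sizes = c(lowland = 15, highland = 14, A = 2,
                                       C = 2, M = 2))
  g <- generate_admixed_genotypes(generate_lineage_frequencies(cfg), cfg)
  pc <- generate_posteriors_and_clines(g$truth, cfg)
  delta_true <- g$truth$alpha$lowland - g$truth$alpha$highland
  r <- cor(pc$clines$steepness, scale(delta_true)[, 1])
  expect_lt(abs(r - 0.1), 0.02)
})

test_that("dependent-correlation comparison reproduces the published statistic", {
  # equal correlations: no evidence either way
  eq <- compare_dependent_correlations(0.4, 0.4, 0.3, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)

  cmp <- compare_dependent_correlations(0.5, 0.3, 0.6, 100)
  expect_equal(cmp$z, oracle_dependent_z(0.5, 0.3, 0.6, 100), tolerance = 1e-10)
  expect_equal(cmp$z, 2.4630997358, tolerance = 1e-9)

  # swapping the compared correlations negates z
  swp <- compare_dependent_correlations(0.3, 0.5, 0.6, 100)
  expect_equal(swp$z, -cmp$z)
  expect_error(compare_dependent_correlations(1, 0.3, 0.2, 50), "degenerate")
  expect_error(compare_dependent_correlations(0.5, 0.3, 0.2, 3), "at least 4")

  # type-I error under a trivariate normal null stays near alpha
  set.seed(8)
  n <- 200
  sigma <- matrix(c(1, .5, .5, .5, 1, .4, .5, .4, 1), 3)
  ch <- chol(sigma)
  rejections <- vapply(1:4000, function(i) {
    x <- matrix(rnorm(3 * n), n) %*% ch
    r <- cor(x)
    compare_dependent_correlations(r[1, 2], r[1, 3], r[2, 3], n)$p < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 1.5 * 0.05)
})

test_that("Fisher exact enumeration matches stats::fisher.test for all margins <= 30", {
  # printed classification table: 11/17 vs 0/4 significant
  tbl <- matrix(c(11, 6, 0, 4), 2, byrow = TRUE)
  p <- fisher_exact_two_sided(tbl)
  expect_equal(p, 0.0350877, tolerance = 1e-5)
  expect_lt(p, 0.05)

  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(matrix(c(4, 6, 2, 3), 2, byrow = TRUE)),
               1, tolerance = 1e-9) # proportional rows

  set.seed(15)
  for (case in 1:300) {
    tbl <- matrix(sample(0:15, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_two_sided(tbl), fisher.test(tbl)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("population classification assembles the table and excludes outliers", {
  comparisons <- tibble::tibble(
    population = sprintf("ext%02d", 1:22),
    A_level = c(runif(11, 0.1, 0.6), runif(6, 0.1, 0.6),
                runif(4, 0.70, 0.84), 0.95),
    z = c(rep(3, 11), rep(0.5, 6), rep(-0.2, 4), 4),
    p = c(rep(1e-5, 11), rep(0.4, 6), rep(0.6, 4), 1e-6)
  )
  out <- classify_and_test(comparisons)
  expect_equal(unname(out$table[1, ]), c(11, 6))
  expect_equal(unname(out$table[2, ]), c(0, 4))
  expect_equal(out$p, 0.0350877, tolerance = 1e-5)
  expect_equal(out$excluded, "ext22")
  expect_equal(glance(out)$p, out$p)
})

test_that("highland ancestry correlates more with highland-like external populations", {
  cfg <- small_config(n_snps = 4000, posterior_noise = 0)
  g <- generate_admixed_genotypes(generate_lineage_frequencies(cfg), cfg)
  pc <- generate_posteriors_and_clines(g$truth, cfg)
  tr <- population_ancestry_track(combine_posterior_A(pc$posteriors))
  wins <- 0
  for (s in 1:20) {
    ext_low_a <- generate_external_population(g$truth, cfg, a_level = 0.6,
                                              seed = 100 + s)
    ext_high_a <- generate_external_population(g$truth, cfg, a_level = 0.8,
                                               seed = 200 + s)
    r_h_low <- cor(tr$pA_highland, ext_low_a$pA)
    r_h_high <- cor(tr$pA_highland, ext_high_a$pA)
    wins <- wins + (r_h_low > r_h_high)
  }
  expect_gte(wins, 18) # sign recovery across seeds
})
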