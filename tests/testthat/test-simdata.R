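test_that("lineage frequencies follow the Balding-Nichols model", {
  cfg0 <- small_config(lineage_divergence = c(A = 1e-14, C = 1e-14, M = 1e-14))
  f0 <- generate_lineage_frequencies(cfg0)
  expect_equal(f0$p_A, f0$p_anc)
  expect_equal(f0$p_C, f0$p_anc)
  expect_equal(f0$p_M, f0$p_anc)

  # higher divergence of A shows up as higher FST against the other lineages
  cfg <- small_config(
    n_snps = 10000, chrom_lengths = c(chr1 = 5e6),
    lineage_divergence = c(A = 0.15, C = 0.05, M = 0.05),
    sample_sizes = c(lowland = 2, highland = 2, A = 30, C = 30, M = 4),
    n_selected_loci = 1
  )
  g <- generate_admixed_genotypes(generate_lineage_frequencies(cfg), cfg)
  fst_ac <- wc_fst_per_snp(g$matrix, "A", "C")
  ok <- !is.na(fst_ac$num)
  # E[(pA - pC)^2] = (F_A + F_C) p(1-p): pairwise FST near 0.10
  expect_gt(sum(fst_ac$num[ok]) / sum(fst_ac$den[ok]), 0.07)
  # C vs M share the low divergence parameter: FST(C,M) ~ 0.1 combined
  fst_cm <- wc_fst_per_snp(g$matrix, "C", "M")
  ok2 <- !is.na(fst_cm$num)
  expect_gt(sum(fst_ac$num[ok]) / sum(fst_ac$den[ok]),
            sum(fst_cm$num[ok2]) / sum(fst_cm$den[ok2]))

  # determinism
  f1 <- generate_lineage_frequencies(small_config(seed = 9L))
  f2 <- generate_lineage_frequencies(small_config(seed = 9L))
  expect_identical(f1, f2)

  expect_error(small_config(lineage_divergence = c(A = 1.2, C = 0.5, M = 0.5)),
               "divergence")
})

test_that("admixed genotypes realize the configured ancestry proportions", {
  sim <- small_sim()
  dos <- sim$truth$a_dosage
  unsel <- setdiff(seq_len(nrow(dos)), sim$truth$selected_idx)
  for (pop in c("lowland", "highland")) {
    cols <- grepl(pop, colnames(dos))
    m <- mean(dos[unsel, cols]) / 2
    alpha <- sim$truth$admix[[pop]]
    se <- sqrt(alpha * (1 - alpha) / (2 * sum(cols) * length(unsel)))
    expect_lt(abs(m - alpha), 3 * se)
  }

  # degenerate mixture: alpha = 1 means every copy is A
  cfg1 <- small_config(n_snps = 200, admix_A_lowland = 0.999, admix_C = 0,
                       n_selected_loci = 0,
                       sample_sizes = c(lowland = 4, highland = 2, A = 2,
                                        C = 2, M = 2))
  cfg1$admix_A_lowland <- 1
  g1 <- generate_admixed_genotypes(generate_lineage_frequencies(cfg1), cfg1)
  low_cols <- grepl("lowland", colnames(g1$truth$a_dosage))
  expect_true(all(g1$truth$a_dosage[, low_cols] == 2))

  # selected loci push highland FST above the genome background
  per <- wc_fst_per_snp(sim$matrix, "lowland", "highland")
  sel <- sim$truth$selected_idx
  expect_gt(mean(per$fst[sel], na.rm = TRUE),
            mean(per$fst[-sel], na.rm = TRUE) + 0.05)
})

test_that("population allele frequencies converge to the mixture expectation", {
  cfg <- small_config(
    n_snps = 500, n_selected_loci = 0, missing_rate = 0,
    sample_sizes = c(lowland = 500, highland = 2, A = 2, C = 2, M = 2)
  )
  f <- generate_lineage_frequencies(cfg)
  g <- generate_admixed_genotypes(f, cfg)
  ac <- allele_counts(g$matrix, samples = "lowland")
  expected <- cfg$admix_A_lowland * f$p_A + cfg$admix_C * f$p_C +
    (1 - cfg$admix_A_lowland - cfg$admix_C) * f$p_M
  se <- sqrt(expected * (1 - expected) / ac$n_alleles)
  expect_lt(mean(abs(ac$alt_freq - expected) / se), 1.5) # E|z| ~ 0.8
  expect_gt(cor(ac$alt_freq, expected), 0.98)
})

test_that("VCF writing honours engineered filter failures and round-trips", {
  sim <- small_sim()
  cfg <- small_config()
  path <- withr::local_tempfile(fileext = ".vcf")

  # no engineered failures: every site passes the hard filters
  wr <- write_vcf(sim, path, cfg)
  hard <- apply_hard_filters(wr$info)
  expect_true(all(hard$pass))

  # engineered QD failures fail exactly the QD rule
  wr2 <- write_vcf(sim, path, cfg, fail_fraction = c(QD = 0.05), seed = 33L)
  hard2 <- apply_hard_filters(wr2$info)
  expect_true(any(!hard2$pass))
  expect_true(all(hard2$reasons[!hard2$pass] == "QD"))
  expect_identical(which(!hard2$pass), which(wr2$info$QD < 2))

  # write -> read reproduces the genotype matrix exactly
  rd <- read_vcf(path)
  expect_identical(rd$matrix$geno, wr2$matrix$geno)
  expect_identical(rd$matrix$samples$ploidy, wr2$matrix$samples$ploidy)

  # byte-identical output under identical config + seed
  path_b <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim, path_b, cfg, fail_fraction = c(QD = 0.05), seed = 33L)
  expect_identical(readLines(path), readLines(path_b))
})

test_that("reference genome carries the GC-depressed centromere signal", {
  cfg <- small_config(chrom_lengths = c(chr1 = 1.5e6), n_snps = 500)
  dir <- withr::local_tempdir()
  ref <- generate_reference_and_genes(cfg, dir)
  gw <- gc_windows(ref$fasta, window_bp = cfg$window_bp)
  ct <- cfg$centromere_truth
  inside <- gw$start >= ct$start[1] & gw$end <= ct$end[1]
  expect_gte(sum(inside), 40)
  expect_lt(mean(gw$gc[inside]), attr(gw, "genome_gc"))

  # zero depression: no systematic dip
  cfg0 <- small_config(chrom_lengths = c(chr1 = 1.5e6), n_snps = 500)
  cfg0$centromere_truth$depth <- 0
  ref0 <- generate_reference_and_genes(cfg0, withr::local_tempdir())
  gw0 <- gc_windows(ref0$fasta, window_bp = cfg0$window_bp)
  inside0 <- gw0$start >= ct$start[1] & gw0$end <= ct$end[1]
  expect_lt(abs(mean(gw0$gc[inside0]) - attr(gw0, "genome_gc")), 0.005)

  # GFF3 round trip preserves the exon count
  back <- read_gene_models(ref$gff)
  expect_equal(nrow(back), nrow(ref$genes))

  # recombination map BED round trip (0-based half-open on disk)
  bed <- read_bed(ref$recomb_bed, c("chrom", "start", "end", "rate"))
  expect_equal(bed$start, ref$recomb$start)
  expect_equal(bed$rate, ref$recomb$rate)
})

test_that("posteriors are valid probability vectors centred on the truth", {
  cfg <- small_config(n_snps = 400,
                      sample_sizes = c(lowland = 4, highland = 4, A = 2,
                                       C = 2, M = 2))
  g <- generate_admixed_genotypes(generate_lineage_frequencies(cfg), cfg)
  pc <- generate_posteriors_and_clines(g$truth, cfg)
  probs <- as.matrix(pc$posteriors[paste0("p", c("CC", "CM", "CA", "MM", "MA", "AA"))])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-12))
  expect_true(all(probs >= 0))

  # noiseless posteriors are exactly the one-hot truth
  cfg0 <- cfg; cfg0$posterior_noise <- 0
  pc0 <- generate_posteriors_and_clines(g$truth, cfg0)
  probs0 <- as.matrix(pc0$posteriors[paste0("p", c("CC", "CM", "CA", "MM", "MA", "AA"))])
  expect_true(all(probs0 %in% c(0, 1)))
  # argmax matches the dosage truth: pA reduction recovers dosage/2
  pa0 <- combine_posterior_A(pc0$posteriors)
  wide <- tidyr::pivot_wider(pa0[c("snp_id", "sample", "pA")],
                             names_from = "sample", values_from = "pA")
  dos <- g$truth$a_dosage[, names(wide)[-1]] / 2
  expect_equal(as.matrix(wide[-1]), dos, ignore_attr = TRUE)

  # zero cline correlation leaves steepness uncorrelated with the truth
  cfgz <- cfg; cfgz$cline_correlation <- 0
  pcz <- generate_posteriors_and_clines(g$truth, cfgz)
  delta <- g$truth$alpha$lowland - g$truth$alpha$highland
  r <- suppressWarnings(cor(pcz$clines$steepness, delta))
  expect_lt(abs(r), 3 / sqrt(nrow(pcz$clines)))
})
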