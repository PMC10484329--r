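#' Configuration for the synthetic admixed-genome generator
#'
#' Defines the study conditions the generator emulates: three divergent
#' source lineages (A = African, C = East European, M = West/Iberian
#' European), two admixed Colombian populations whose mean A-ancestry
#' proportions default to the elevational contrast (0.847 lowland vs 0.686
#' highland), a minority of selected loci where highland A ancestry is shifted
#' further, haploid drones carried diploid-coded in the VCF, GC-depleted
#' pericentromeric tracts in the reference, and noisy diplotype ancestry
#' posteriors.
#'
#' @param n_snps Number of SNPs to simulate.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param window_bp Window size in bp used downstream (kept with the config so
#'   the recombination map and truth windows line up).
#' @param lineage_divergence Named vector `c(A=, C=, M=)` of Balding-Nichols
#'   drift parameters in (0, 1); each equals the expected FST of that lineage
#'   to the shared ancestral frequency. Cross-lineage heterozygosity equals
#'   ancestral heterozygosity under this model, so the A lineage out-diversifies
#'   the admixed populations only when `F_A < F_M (1-alpha)/(1+alpha)`; the
#'   defaults (A = 0.02, C = 0.70, M = 0.65) reproduce the observed diversity
#'   ordering A > admixed > M > C with margin.
#' @param admix_A_lowland,admix_A_highland Mean A-ancestry proportion per
#'   allele copy in the two admixed populations.
#' @param admix_C Minority C-lineage contribution per allele copy.
#' @param n_selected_loci Number of selection-target loci (mutually separated
#'   by at least three windows so each sits in its own scan window).
#' @param selection_region_bp Width of the ancestry-shifted region centred on
#'   each selected locus. Selected ancestry tracts span multiple scan windows
#'   (empirical peaks run from tens to hundreds of kb); the default of three
#'   windows guarantees one fully shifted window per target with partially
#'   shifted flanks for the peak extension to absorb.
#' @param selection_ancestry_shift Reduction of the highland A proportion at
#'   selected loci (must leave the proportion in `[0, 1]`).
#' @param sample_sizes Named vector of samples per population
#'   (`lowland`, `highland`, `A`, `C` diploid; `M` haploid drones).
#' @param centromere_truth Tibble with one row per chromosome: `chrom`,
#'   `start`, `end`, `depth` (GC depression, subtracted from the background GC
#'   fraction inside the interval).
#' @param gc_background Genome background GC fraction.
#' @param posterior_noise Dirichlet noise level for ancestry posteriors
#'   (0 = noiseless one-hot posteriors; larger = noisier).
#' @param cline_correlation Target correlation between simulated cline
#'   steepness and the true per-SNP ancestry shift.
#' @param het_drone_rate1,het_drone_rate2 Fractions of sites given one / two
#'   artifactual heterozygous drone calls when writing the VCF.
#' @param missing_rate Per-genotype missingness rate in the written VCF.
#' @param seed Integer master seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 40000,
                       chrom_lengths = c(chr1 = 4e6, chr2 = 4e6, chr3 = 4e6,
                                         chr4 = 4e6, chr5 = 4e6),
                       window_bp = 10000,
                       lineage_divergence = c(A = 0.02, C = 0.70, M = 0.65),
                       admix_A_lowland = 0.847,
                       admix_A_highland = 0.686,
                       admix_C = 0.001,
                       n_selected_loci = 4,
                       selection_region_bp = 30000,
                       selection_ancestry_shift = 0.5,
                       sample_sizes = c(lowland = 15, highland = 14,
                                        A = 19, C = 9, M = 85),
                       centromere_truth = NULL,
                       gc_background = 0.35,
                       posterior_noise = 0.05,
                       cline_correlation = 0.1,
                       het_drone_rate1 = 0.025,
                       het_drone_rate2 = 0.005,
                       missing_rate = 0.02,
                       seed = 1L) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (is.null(centromere_truth)) {
    centromere_truth <- tibble::tibble(
      chrom = names(chrom_lengths),
      start = floor(chrom_lengths * 0.3) + 1,
      end = floor(chrom_lengths * 0.6),
      depth = 0.15
    )
  }
  cfg <- list(
    n_snps = as.integer(n_snps), chrom_lengths = chrom_lengths,
    window_bp = window_bp, lineage_divergence = lineage_divergence,
    admix_A_lowland = admix_A_lowland, admix_A_highland = admix_A_highland,
    admix_C = admix_C, n_selected_loci = as.integer(n_selected_loci),
    selection_region_bp = selection_region_bp,
    selection_ancestry_shift = selection_ancestry_shift,
    sample_sizes = sample_sizes, centromere_truth = tibble::as_tibble(centromere_truth),
    gc_background = gc_background, posterior_noise = posterior_noise,
    cline_correlation = cline_correlation,
    het_drone_rate1 = het_drone_rate1, het_drone_rate2 = het_drone_rate2,
    missing_rate = missing_rate, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  props <- c(cfg$admix_A_lowland, cfg$admix_A_highland, cfg$admix_C,
             cfg$selection_ancestry_shift, cfg$gc_background)
  if (any(props < 0 | props > 1)) abort("all proportions must lie in [0, 1]")
  if (any(cfg$lineage_divergence <= 0 | cfg$lineage_divergence >= 1)) {
    abort("lineage divergence parameters must lie strictly in (0, 1)")
  }
  if (cfg$n_snps < 1) abort("n_snps must be >= 1")
  if (cfg$admix_A_highland - cfg$selection_ancestry_shift < 0) {
    abort("selection_ancestry_shift pushes the highland A proportion below 0")
  }
  dip <- cfg$sample_sizes[c("lowland", "highland", "A", "C")]
  if (any(dip < 2)) abort("diploid populations need at least 2 samples")
  ct <- cfg$centromere_truth
  lens <- cfg$chrom_lengths[ct$chrom]
  if (any(is.na(lens)) || any(ct$start < 1) || any(ct$end > lens)) {
    abort("centromere truth intervals must lie within chromosome bounds")
  }
  invisible(cfg)
}

# distribute SNP positions across chromosomes, proportional to length
sim_positions <- function(cfg) {
  lens <- cfg$chrom_lengths
  n_per <- round(cfg$n_snps * lens / sum(lens))
  n_per[length(n_per)] <- cfg$n_snps - sum(n_per[-length(n_per)])
  purrr::imap(n_per, function(n, chr) {
    tibble::tibble(chrom = chr, pos = sort(sample.int(lens[[chr]], n)))
  }) |>
    purrr::list_rbind()
}

#' Draw per-SNP lineage allele frequencies (Balding-Nichols model)
#'
#' Each lineage's frequency is drawn from a Beta distribution centred on a
#' shared ancestral frequency `p ~ U(0.05, 0.95)` with shape
#' `p(1-F)/F, (1-p)(1-F)/F`, where `F` is that lineage's divergence
#' parameter. SNPs monomorphic in all three lineages are rejected and redrawn.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return Tibble: `chrom`, `pos`, `p_anc`, `p_A`, `p_C`, `p_M`.
#' @export
generate_lineage_frequencies <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(seed)
  sites <- sim_positions(config)
  n <- nrow(sites)
  p <- runif(n, 0.05, 0.95)
  draw <- function(Fdiv) {
    if (Fdiv < 1e-12) return(p)
    rbeta(n, p * (1 - Fdiv) / Fdiv, (1 - p) * (1 - Fdiv) / Fdiv)
  }
  Fv <- config$lineage_divergence
  pA <- draw(Fv[["A"]]); pC <- draw(Fv[["C"]]); pM <- draw(Fv[["M"]])
  # reject SNPs monomorphic in all lineages simultaneously
  repeat {
    mono <- (pA == 0 & pC == 0 & pM == 0) | (pA == 1 & pC == 1 & pM == 1)
    if (!any(mono)) break
    k <- which(mono)
    p[k] <- runif(length(k), 0.05, 0.95)
    for (lin in c("A", "C", "M")) {
      Fd <- Fv[[lin]]
      v <- rbeta(length(k), p[k] * (1 - Fd) / Fd, (1 - p[k]) * (1 - Fd) / Fd)
      if (lin == "A") pA[k] <- v else if (lin == "C") pC[k] <- v else pM[k] <- v
    }
  }
  dplyr::mutate(sites, p_anc = p, p_A = pA, p_C = pC, p_M = pM)
}

pop_ids <- function(pop, n) sprintf("%s_%02d", pop, seq_len(n))

#' Simulate genotypes for the five study populations
#'
#' Admixed (Colombian) individuals draw the ancestry of each allele copy
#' independently: A with the population's proportion, C with a small fixed
#' proportion, M otherwise; the allele is then drawn from that lineage's
#' frequency. At selected loci the highland A proportion is reduced by
#' `selection_ancestry_shift`. Reference populations are pure-lineage; the M
#' drones are haploid (diploid-coded as homozygotes).
#'
#' @param freqs Output of [generate_lineage_frequencies()].
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return List with `matrix` (a [snp_matrix()]) and `truth` (list: selected
#'   loci, per-copy ancestries and A-dosages of the admixed individuals,
#'   admixture proportions, the input frequencies, centromere truth).
#' @export
generate_admixed_genotypes <- function(freqs, config, seed = config$seed + 1L) {
  validate_sim_config(config)
  set.seed(seed)
  n <- nrow(freqs)
  sz <- config$sample_sizes
  # selected-locus centres, mutually separated by > 3 windows
  min_gap <- 3 * config$window_bp
  centers <- integer(0)
  for (i in sample.int(n)) {
    if (length(centers) >= config$n_selected_loci) break
    clash <- any(freqs$chrom[centers] == freqs$chrom[i] &
                   abs(freqs$pos[centers] - freqs$pos[i]) <= min_gap)
    if (!clash) centers <- c(centers, i)
  }
  centers <- sort(centers)
  half <- config$selection_region_bp / 2
  shifted <- rep(FALSE, n)
  for (i in centers) {
    shifted <- shifted | (freqs$chrom == freqs$chrom[i] &
                            abs(freqs$pos - freqs$pos[i]) <= half)
  }
  selected <- which(shifted)

  alpha_low <- rep(config$admix_A_lowland, n)
  alpha_high <- rep(config$admix_A_highland, n)
  alpha_high[selected] <- alpha_high[selected] - config$selection_ancestry_shift
  if (any(alpha_high < 0)) abort("shifted highland A proportion fell below 0")

  draw_admixed <- function(n_ind, alpha_A) {
    # per allele copy: lineage then allele; lineages coded 1=C, 2=M, 3=A
    lin <- matrix(0L, n, 2 * n_ind)
    all_ <- matrix(0L, n, 2 * n_ind)
    for (j in seq_len(2 * n_ind)) {
      u <- runif(n)
      lj <- ifelse(u < alpha_A, 3L, ifelse(u < alpha_A + config$admix_C, 1L, 2L))
      pj <- ifelse(lj == 3L, freqs$p_A, ifelse(lj == 1L, freqs$p_C, freqs$p_M))
      lin[, j] <- lj
      all_[, j] <- as.integer(runif(n) < pj)
    }
    list(lineage = lin, allele = all_)
  }

  low <- draw_admixed(sz[["lowland"]], alpha_low)
  high <- draw_admixed(sz[["highland"]], alpha_high)

  pair_cols <- function(m) m[, seq(1, ncol(m), 2), drop = FALSE] +
    m[, seq(2, ncol(m), 2), drop = FALSE]

  g_low <- pair_cols(low$allele)
  g_high <- pair_cols(high$allele)
  g_A <- matrix(rbinom(n * sz[["A"]], 2, freqs$p_A), n)
  g_C <- matrix(rbinom(n * sz[["C"]], 2, freqs$p_C), n)
  g_M <- 2L * matrix(rbinom(n * sz[["M"]], 1, freqs$p_M), n)

  geno <- cbind(g_low, g_high, g_A, g_C, g_M)
  samples <- tibble::tibble(
    id = c(pop_ids("lowland", sz[["lowland"]]), pop_ids("highland", sz[["highland"]]),
           pop_ids("A", sz[["A"]]), pop_ids("C", sz[["C"]]), pop_ids("M", sz[["M"]])),
    population = rep(c("lowland", "highland", "A", "C", "M"),
                     times = sz[c("lowland", "highland", "A", "C", "M")]),
    ploidy = rep(c(2L, 2L, 2L, 2L, 1L),
                 times = sz[c("lowland", "highland", "A", "C", "M")])
  )
  sites <- random_alleles(freqs[c("chrom", "pos")])
  mat <- snp_matrix(sites, geno, samples)

  a_dosage <- cbind(pair_cols(low$lineage == 3L), pair_cols(high$lineage == 3L))
  colnames(a_dosage) <- samples$id[samples$population %in% c("lowland", "highland")]
  truth <- list(
    freqs = freqs,
    selected_idx = selected,
    selected = freqs[centers, c("chrom", "pos")],
    selected_snps = freqs[selected, c("chrom", "pos")],
    alpha = list(lowland = alpha_low, highland = alpha_high),
    admix = c(lowland = config$admix_A_lowland, highland = config$admix_A_highland),
    a_dosage = a_dosage,
    copy_lineage = list(
      lowland = low$lineage, highland = high$lineage,
      ids = list(lowland = pop_ids("lowland", sz[["lowland"]]),
                 highland = pop_ids("highland", sz[["highland"]]))
    ),
    centromeres = config$centromere_truth
  )
  list(matrix = mat, truth = truth)
}

random_alleles <- function(sites) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nrow(sites), replace = TRUE)
  alt <- sample(bases[-1], nrow(sites), replace = TRUE)
  alt <- ifelse(alt == ref, "A", alt)
  dplyr::mutate(sites, ref = ref, alt = alt)
}

#' Run the full genotype simulation in one call
#'
#' @param config A [sim_config()].
#' @return As [generate_admixed_genotypes()], plus the config.
#' @export
simulate_study <- function(config = sim_config()) {
  freqs <- generate_lineage_frequencies(config)
  out <- generate_admixed_genotypes(freqs, config)
  out$config <- config
  out
}

#' Write a simulated panel to VCF 4.2, with site annotations
#'
#' Emits a joint-called-style VCF: INFO fields `QD, FS, MQ, MQRankSum,
#' ReadPosRankSum, SOR`, site `QUAL`, and per-sample `GT:DP`. Haploid drones
#' are diploid-coded homozygotes except an injected fraction of artifactual
#' heterozygous drone calls. A configurable fraction of sites is engineered to
#' fail each hard-filter rule; the remainder are drawn from safely-passing
#' ranges. Returns (invisibly) the matrix as written, so round-trips can be
#' checked exactly.
#'
#' @param sim Output of [simulate_study()] / [generate_admixed_genotypes()],
#'   or a bare [snp_matrix()].
#' @param path Output VCF path.
#' @param config A [sim_config()] (for injection rates and chromosome lengths).
#' @param fail_fraction Named vector of engineered failure fractions over
#'   `QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR, QUAL, DP`; default all 0.
#' @param seed Optional seed override.
#' @return Invisibly, a list: `path`, `matrix` (with injected drone hets and
#'   missingness), `info` (annotations as written).
#' @export
write_vcf <- function(sim, path, config = sim$config,
                      fail_fraction = c(), seed = config$seed + 2L) {
  mat <- if (inherits(sim, "snp_matrix")) sim else sim$matrix
  set.seed(seed)
  n <- nrow(mat$sites)
  ns <- nrow(mat$samples)

  ff <- c(QD = 0, FS = 0, MQ = 0, MQRankSum = 0, ReadPosRankSum = 0,
          SOR = 0, QUAL = 0, DP = 0)
  ff[names(fail_fraction)] <- fail_fraction

  engineered <- function(frac) runif(n) < frac
  pick <- function(frac, pass, fail) ifelse(engineered(frac), fail(n), pass(n))
  info <- tibble::tibble(
    QD = pick(ff["QD"], \(n) runif(n, 5, 35), \(n) runif(n, 0.1, 1.9)),
    FS = pick(ff["FS"], \(n) runif(n, 0, 30), \(n) runif(n, 61, 120)),
    MQ = pick(ff["MQ"], \(n) runif(n, 50, 60), \(n) runif(n, 20, 39)),
    MQRankSum = pick(ff["MQRankSum"], \(n) runif(n, -3, 3), \(n) runif(n, -20, -12.6)),
    ReadPosRankSum = pick(ff["ReadPosRankSum"], \(n) runif(n, -3, 3), \(n) runif(n, -12, -8.1)),
    SOR = pick(ff["SOR"], \(n) runif(n, 0.5, 2.5), \(n) runif(n, 3.1, 6)),
    QUAL = pick(ff["QUAL"], \(n) runif(n, 150, 3000), \(n) runif(n, 20, 100))
  )
  dp_high <- engineered(ff["DP"])
  dp <- matrix(rpois(n * ns, 10), n, ns)
  if (any(dp_high)) dp[dp_high, ] <- rpois(sum(dp_high) * ns, 35)

  geno <- mat$geno
  # artifactual heterozygous drone calls
  drones <- which(mat$samples$ploidy == 1L)
  if (length(drones) > 0) {
    r1 <- config$het_drone_rate1
    r2 <- config$het_drone_rate2
    u <- runif(n)
    one <- which(u < r1)
    two <- which(u >= r1 & u < r1 + r2)
    for (i in one) geno[i, sample(drones, 1)] <- 1L
    for (i in two) geno[i, sample(drones, 2)] <- 1L
  }
  # missingness
  miss <- matrix(runif(n * ns) < config$missing_rate, n, ns)
  geno[miss] <- NA_integer_

  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", n, ns)
  ok <- !is.na(geno)
  gt[ok] <- gt_code[as.character(geno[ok])]
  cells <- matrix(paste0(gt, ":", dp), n, ns)
  body <- paste(
    mat$sites$chrom, mat$sites$pos, ".", mat$sites$ref, mat$sites$alt,
    sprintf("%.2f", info$QUAL), "PASS",
    sprintf("QD=%.4g;FS=%.4g;MQ=%.4g;MQRankSum=%.4g;ReadPosRankSum=%.4g;SOR=%.4g",
            info$QD, info$FS, info$MQ, info$MQRankSum, info$ReadPosRankSum, info$SOR),
    "GT:DP",
    apply(cells, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  lens <- config$chrom_lengths
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=beescan-simdata",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QualByDepth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMSMappingQuality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQRankSum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"ReadPosRankSum\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"StrandOddsRatio\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", mat$samples$id), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)

  out_mat <- snp_matrix(mat$sites, geno, mat$samples)
  invisible(list(path = path, matrix = out_mat,
                 info = dplyr::mutate(info, dp_mean = rowMeans(dp))))
}

#' Read a VCF into a SNP panel with site annotations
#'
#' Parses with vcfR. Sample populations default to the prefix of the sample
#' id before the last underscore; populations listed in `haploid_pops` are
#' flagged haploid.
#'
#' @param path VCF path.
#' @param samples Optional samples tibble (`id`, `population`, `ploidy`)
#'   overriding the name-derived metadata.
#' @param haploid_pops Populations to flag as haploid.
#' @return List of class `vcf_data`: `matrix` ([snp_matrix()]), `info`
#'   (tibble: QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR, QUAL), `dp`
#'   (numeric matrix of per-sample depths).
#' @export
read_vcf <- function(path, samples = NULL, haploid_pops = "M") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dosage[gt %in% c("0/0", "0|0")] <- 0L
  dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt %in% c("1/1", "1|1")] <- 2L
  dosage[gt %in% c("0")] <- 0L
  dosage[gt %in% c("1")] <- 2L

  ids <- colnames(gt)
  if (is.null(samples)) {
    pop <- sub("_[^_]*$", "", ids)
    samples <- tibble::tibble(
      id = ids, population = pop,
      ploidy = ifelse(pop %in% haploid_pops, 1L, 2L)
    )
  }
  info_field <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  info <- tibble::tibble(
    QD = info_field("QD"), FS = info_field("FS"), MQ = info_field("MQ"),
    MQRankSum = info_field("MQRankSum"),
    ReadPosRankSum = info_field("ReadPosRankSum"), SOR = info_field("SOR"),
    QUAL = suppressWarnings(as.numeric(fix$QUAL))
  )
  sites <- tibble::tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT
  )
  structure(
    list(matrix = snp_matrix(sites, dosage, samples), info = info, dp = dp),
    class = "vcf_data"
  )
}

#' Generate a reference genome, gene models and recombination map
#'
#' The FASTA has iid bases at the configured background GC fraction, depressed
#' by `depth` inside each true centromere interval. Gene models (multi-exon,
#' both strands) are written as GFF3; when `truth` is supplied, one gene is
#' placed over each of the first selected loci so that downstream peak calls
#' have annotatable targets. The recombination map tiles the genome at
#' `window_bp` resolution with reduced rates in centromeres (x0.3) and in
#' windows containing selected loci (x0.39).
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param truth Optional truth list from [generate_admixed_genotypes()].
#' @param n_genes Number of random background genes.
#' @param seed Optional seed override.
#' @return List: `fasta`, `gff`, `recomb_bed` (paths), `genes` (exon tibble),
#'   `recomb` (tibble: chrom, start, end, rate; 1-based inclusive).
#' @export
generate_reference_and_genes <- function(config, dir, truth = NULL,
                                         n_genes = 150, seed = config$seed + 3L) {
  validate_sim_config(config)
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lens <- config$chrom_lengths
  ct <- config$centromere_truth

  base_at <- c("A", "T"); base_gc <- c("G", "C")
  seqs <- purrr::imap(lens, function(len, chr) {
    gc <- rep(config$gc_background, len)
    row <- ct[ct$chrom == chr, ]
    if (nrow(row) == 1) gc[row$start:row$end] <- config$gc_background - row$depth
    is_gc <- runif(len) < gc
    s <- character(len)
    s[is_gc] <- sample(base_gc, sum(is_gc), replace = TRUE)
    s[!is_gc] <- sample(base_at, sum(!is_gc), replace = TRUE)
    paste(s, collapse = "")
  })
  fasta <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- names(lens)
  Biostrings::writeXStringSet(dna, fasta, width = 60)

  make_gene <- function(gid, chr, anchor = NULL) {
    n_ex <- sample(3:8, 1)
    ex_len <- sample(150:500, n_ex, replace = TRUE)
    gaps <- sample(100:2000, n_ex - 1, replace = TRUE)
    span <- sum(ex_len) + sum(gaps)
    start <- if (is.null(anchor)) {
      sample.int(max(1, lens[[chr]] - span), 1)
    } else {
      max(1, min(anchor - sample.int(span, 1) + 1, lens[[chr]] - span))
    }
    starts <- start + cumsum(c(0, head(ex_len, -1) + gaps))
    tibble::tibble(
      gene_id = gid, chrom = chr, strand = sample(c("+", "-"), 1),
      exon = seq_len(n_ex), start = starts, end = starts + ex_len - 1
    )
  }
  genes <- purrr::map(seq_len(n_genes), function(i) {
    make_gene(sprintf("gene%04d", i), sample(names(lens), 1))
  })
  if (!is.null(truth)) {
    sel <- truth$selected
    k <- min(nrow(sel), 10)
    genes <- c(genes, purrr::map(seq_len(k), function(i) {
      make_gene(sprintf("selgene%02d", i), sel$chrom[i], anchor = sel$pos[i])
    }))
  }
  genes <- purrr::list_rbind(genes)

  gff <- file.path(dir, "genes.gff3")
  write_gff3(genes, gff)

  w <- config$window_bp
  recomb <- purrr::imap(lens, function(len, chr) {
    starts <- seq(1, len, by = w)
    tibble::tibble(chrom = chr, start = starts,
                   end = pmin(starts + w - 1, len), rate = 25)
  }) |> purrr::list_rbind()
  for (i in seq_len(nrow(ct))) {
    hit <- recomb$chrom == ct$chrom[i] & recomb$start <= ct$end[i] & recomb$end >= ct$start[i]
    recomb$rate[hit] <- recomb$rate[hit] * 0.3
  }
  if (!is.null(truth)) {
    for (i in seq_len(nrow(truth$selected))) {
      hit <- recomb$chrom == truth$selected$chrom[i] &
        recomb$start <= truth$selected$pos[i] & recomb$end >= truth$selected$pos[i]
      recomb$rate[hit] <- recomb$rate[hit] * 0.39
    }
  }
  bed <- file.path(dir, "recomb.bed")
  readr::write_tsv(
    dplyr::transmute(recomb, .data$chrom, start = .data$start - 1L,
                     end = .data$end, rate = .data$rate),
    bed, col_names = FALSE
  )
  list(fasta = fasta, gff = gff, recomb_bed = bed, genes = genes, recomb = recomb)
}

write_gff3 <- function(exons, path) {
  gene_rows <- exons |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(gene_rows))) {
    g <- gene_rows[i, ]
    lines <- c(lines, paste(g$chrom, "beescan", "gene", g$start, g$end, ".",
                            g$strand, ".", sprintf("ID=%s", g$gene_id), sep = "\t"))
    ex <- exons[exons$gene_id == g$gene_id, ]
    lines <- c(lines, paste(ex$chrom, "beescan", "exon", ex$start, ex$end, ".",
                            ex$strand, ".",
                            sprintf("ID=%s.e%d;Parent=%s", ex$gene_id, ex$exon, ex$gene_id),
                            sep = "\t"))
  }
  writeLines(lines, path)
}

#' Read gene models (exons) from a GFF3 file
#'
#' @param path GFF3 path.
#' @return Exon tibble: `gene_id`, `chrom`, `strand`, `exon`, `start`, `end`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parent <- as.character(unlist(ex$Parent))
  tibble::tibble(
    gene_id = parent,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex)
  ) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(exon = dplyr::row_number()) |>
    dplyr::ungroup()
}

diplotype_states <- c("CC", "CM", "CA", "MM", "MA", "AA")

# unordered pair of per-copy lineages (1=C,2=M,3=A) -> state index
state_index <- function(l1, l2) {
  a <- pmin(l1, l2); b <- pmax(l1, l2)
  dplyr::case_when(
    a == 1 & b == 1 ~ 1L, a == 1 & b == 2 ~ 2L, a == 1 & b == 3 ~ 3L,
    a == 2 & b == 2 ~ 4L, a == 2 & b == 3 ~ 5L, a == 3 & b == 3 ~ 6L
  )
}

#' Simulate diplotype ancestry posteriors and a cline-steepness table
#'
#' For each SNP x admixed individual, a 6-state probability vector over
#' diplotype ancestries (CC, CM, CA, MM, MA, AA) is drawn from a Dirichlet
#' centred on the true diplotype: `alpha = 0.5 + I(true)/noise`. As the noise
#' level goes to 0 the posterior becomes the exact one-hot truth. Cline
#' steepness is generated with the configured correlation to the true per-SNP
#' ancestry shift (lowland minus highland A proportion).
#'
#' @param truth Truth list from [generate_admixed_genotypes()].
#' @param config A [sim_config()].
#' @param seed Optional seed override.
#' @return List: `posteriors` (tibble: snp_id, chrom, pos, sample, population,
#'   pCC..pAA), `clines` (tibble: snp_id, chrom, pos, steepness).
#' @export
generate_posteriors_and_clines <- function(truth, config, seed = config$seed + 4L) {
  set.seed(seed)
  freqs <- truth$freqs
  n <- nrow(freqs)
  snp_id <- paste0(freqs$chrom, ":", freqs$pos)

  rows <- purrr::imap(truth$copy_lineage$ids, function(ids, pop) {
    lin <- truth$copy_lineage[[pop]]
    purrr::imap(ids, function(id, j) {
      tibble::tibble(
        snp_id = snp_id, chrom = freqs$chrom, pos = freqs$pos,
        sample = id, population = pop,
        state = state_index(lin[, 2 * j - 1], lin[, 2 * j])
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  N <- nrow(rows)
  if (config$posterior_noise <= 0) {
    probs <- matrix(0, N, 6)
    probs[cbind(seq_len(N), rows$state)] <- 1
  } else {
    kappa <- 1 / config$posterior_noise
    probs <- matrix(rgamma(N * 6, shape = 0.5), N, 6)
    probs[cbind(seq_len(N), rows$state)] <-
      rgamma(N, shape = 0.5 + kappa)
    probs <- probs / rowSums(probs)
  }
  colnames(probs) <- paste0("p", diplotype_states)
  posteriors <- dplyr::bind_cols(rows[setdiff(names(rows), "state")],
                                 tibble::as_tibble(probs))

  delta_true <- truth$alpha$lowland - truth$alpha$highland
  z <- if (sd(delta_true) > 0) as.numeric(scale(delta_true)) else rep(0, n)
  rho <- config$cline_correlation
  steep <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  clines <- tibble::tibble(snp_id = snp_id, chrom = freqs$chrom,
                           pos = freqs$pos, steepness = steep)
  list(posteriors = posteriors, clines = clines)
}

#' Expected per-bp nucleotide diversity of a simulated lineage panel
#'
#' Closed-form expectation under the generator: SNP density times the expected
#' per-SNP heterozygosity `2 E[p(1-p)] (1-F)` of the Balding-Nichols draw,
#' with `p ~ U(0.05, 0.95)`.
#'
#' @param config A [sim_config()].
#' @param lineage One of "A", "C", "M".
#' @return Expected pi per bp.
#' @export
expected_pi <- function(config, lineage = "A") {
  Fd <- config$lineage_divergence[[lineage]]
  # E[2p(1-p)] for p ~ U(a, b)
  a <- 0.05; b <- 0.95
  e_p <- (a + b) / 2
  e_p2 <- (b^3 - a^3) / (3 * (b - a))
  h <- 2 * (e_p - e_p2) * (1 - Fd)
  h * config$n_snps / sum(config$chrom_lengths)
}

#' Simulate the A-ancestry track of an external reference population
#'
#' Emulates a hybrid-zone population with genome-wide A ancestry `a_level`
#' that shares the panel's selection targets: at selected loci its A
#' proportion is depressed by the configured shift scaled by how
#' highland-like the population is (linearly from 0 at the lowland level to
#' the full shift at the highland level and below). The returned track is the
#' per-SNP mean A dosage / ploidy over `n_ind` simulated individuals.
#'
#' @param truth Truth list from [generate_admixed_genotypes()].
#' @param config A [sim_config()].
#' @param a_level Genome-wide A-ancestry proportion of the population.
#' @param n_ind Number of diploid individuals.
#' @param seed Integer seed.
#' @return Tibble: `snp_id`, `chrom`, `pos`, `pA`.
#' @export
generate_external_population <- function(truth, config, a_level, n_ind = 20,
                                         seed = 1L) {
  set.seed(seed)
  n <- nrow(truth$freqs)
  scale <- min(1, max(0, (config$admix_A_lowland - a_level) /
                        (config$admix_A_lowland - config$admix_A_highland)))
  alpha <- rep(a_level, n)
  alpha[truth$selected_idx] <- pmax(
    0, alpha[truth$selected_idx] - scale * config$selection_ancestry_shift
  )
  dosage <- matrix(rbinom(n * n_ind, 2, alpha), n, n_ind)
  tibble::tibble(
    snp_id = paste0(truth$freqs$chrom, ":", truth$freqs$pos),
    chrom = truth$freqs$chrom, pos = truth$freqs$pos,
    pA = rowMeans(dosage) / 2
  )
}
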