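#' GATK-style hard filters on site annotations
#'
#' A site fails if any rule triggers: `QD < 2`, `FS > 60`, `MQ < 40`,
#' `MQRankSum < -12.5`, `ReadPosRankSum < -8`, `SOR > 3`. Comparators are
#' strict exactly as printed, so boundary values pass. Missing annotations do
#' not fail their rule (callers omit rank-sum annotations at
#' homozygous-only sites).
#'
#' @param info Tibble with numeric columns `QD`, `FS`, `MQ`, `MQRankSum`,
#'   `ReadPosRankSum`, `SOR` (missing columns are treated as all-NA).
#' @return Tibble: `pass` (logical) and `reasons` (comma-separated triggered
#'   rules, `""` when passing).
#' @export
apply_hard_filters <- function(info) {
  rules <- list(
    QD = function(x) x < 2,
    FS = function(x) x > 60,
    MQ = function(x) x < 40,
    MQRankSum = function(x) x < -12.5,
    ReadPosRankSum = function(x) x < -8,
    SOR = function(x) x > 3
  )
  n <- nrow(info)
  hits <- matrix(FALSE, n, length(rules), dimnames = list(NULL, names(rules)))
  for (key in names(rules)) {
    if (!key %in% names(info)) next
    x <- info[[key]]
    if (!is.numeric(x)) {
      bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
      abort(paste0("non-numeric ", key, " annotation at site row ", bad[1]))
    }
    hit <- rules[[key]](x)
    hit[is.na(hit)] <- FALSE
    hits[, key] <- hit
  }
  reasons <- apply(hits, 1, function(r) paste(names(rules)[r], collapse = ","))
  tibble::tibble(pass = !apply(hits, 1, any), reasons = reasons)
}

#' Site-level filters: bi-allelic SNPs, QUAL, depth, missingness
#'
#' Retains bi-allelic SNPs (single-base ref and alt) with `QUAL > 100`
#' (strict), mean per-sample depth `<= 20` (inclusive; sites with no depth
#' values skip the rule), and per-population missingness `< 30%` in every
#' population.
#'
#' @param vcf A `vcf_data` list from [read_vcf()] (fields `matrix`, `info`,
#'   `dp`), with hard filters already applied via `hard_pass`.
#' @param hard_pass Optional logical vector from [apply_hard_filters()];
#'   failing sites are removed first.
#' @param max_mean_dp Inclusive mean-depth ceiling.
#' @param min_qual Strict QUAL floor.
#' @param max_missing Missingness threshold; a site is removed when the
#'   missing fraction is `>=` this value in any population.
#' @return List: `matrix` (filtered [snp_matrix()]), `info`, `dp` (subset
#'   alongside), `log` (tibble of removal counts by reason).
#' @export
apply_site_filters <- function(vcf, hard_pass = NULL, max_mean_dp = 20,
                               min_qual = 100, max_missing = 0.30) {
  mat <- vcf$matrix
  pops <- unique(mat$samples$population)
  n <- nrow(mat$sites)
  keep <- rep(TRUE, n)
  log <- list()
  note <- function(reason, removed) {
    log[[length(log) + 1]] <<- tibble::tibble(reason = reason, removed = sum(removed))
  }

  if (!is.null(hard_pass)) {
    drop <- !hard_pass
    note("hard_filter", drop & keep); keep <- keep & !drop
  }
  biallelic <- nchar(mat$sites$ref) == 1 & nchar(mat$sites$alt) == 1 &
    mat$sites$ref %in% c("A", "C", "G", "T") & mat$sites$alt %in% c("A", "C", "G", "T")
  note("not_biallelic_snp", !biallelic & keep); keep <- keep & biallelic

  qual_ok <- !is.na(vcf$info$QUAL) & vcf$info$QUAL > min_qual
  note("low_qual", !qual_ok & keep); keep <- keep & qual_ok

  if (!is.null(vcf$dp)) {
    mean_dp <- rowMeans(vcf$dp, na.rm = TRUE)
    dp_ok <- is.nan(mean_dp) | mean_dp <= max_mean_dp
    note("high_depth", !dp_ok & keep); keep <- keep & dp_ok
  }

  miss_ok <- rep(TRUE, n)
  for (p in pops) {
    cols <- mat$samples$population == p
    if (!any(cols)) abort(paste0("unknown population label: ", p))
    frac <- rowMeans(is.na(mat$geno[, cols, drop = FALSE]))
    miss_ok <- miss_ok & (frac < max_missing)
  }
  note("missingness", !miss_ok & keep); keep <- keep & miss_ok

  list(
    matrix = snp_subset(mat, sites = which(keep)),
    info = vcf$info[keep, ],
    dp = if (is.null(vcf$dp)) NULL else vcf$dp[keep, , drop = FALSE],
    keep = keep,
    log = purrr::list_rbind(log)
  )
}

#' Resolve heterozygous calls in haploid drones
#'
#' Drones are haploid, so heterozygous diploid-coded calls are genotyping
#' artifacts: at sites where exactly one drone is heterozygous that genotype
#' is set missing; sites where two or more drones are heterozygous are
#' removed entirely.
#'
#' @param mat A [snp_matrix()] with haploid samples flagged in the metadata.
#' @return List: `matrix`, `log` (tibble: sites_one_het, sites_multi_het
#'   removed, genotypes_masked).
#' @export
handle_drone_heterozygotes <- function(mat) {
  drones <- which(mat$samples$ploidy == 1L)
  if (length(drones) == 0) {
    abort("matrix declares no haploid samples; drone handling needs drones")
  }
  g <- mat$geno
  het <- g[, drones, drop = FALSE] == 1L
  het[is.na(het)] <- FALSE
  n_het <- rowSums(het)
  one <- n_het == 1L
  multi <- n_het >= 2L
  if (any(one)) {
    idx <- which(one)
    for (i in idx) g[i, drones[het[i, ]]] <- NA_integer_
  }
  keep <- !multi
  out <- snp_matrix(mat$sites[keep, ], g[keep, , drop = FALSE], mat$samples)
  list(
    matrix = out,
    keep = keep,
    log = tibble::tibble(
      sites_one_het = sum(one), sites_multi_het_removed = sum(multi),
      genotypes_masked = sum(one)
    )
  )
}

#' Minor allele count filter
#'
#' Removes sites whose minor allele count (over called genotypes; haploids
#' contribute one allele copy) is below `min_count`. All-missing sites have
#' MAC 0 and are removed.
#'
#' @param mat A [snp_matrix()].
#' @param min_count Minimum minor allele count to retain (default 3).
#' @return List: `matrix`, `keep` (logical).
#' @export
mac_filter <- function(mat, min_count = 3) {
  ac <- allele_counts(mat)
  mac <- pmin(ac$alt_count, ac$n_alleles - ac$alt_count)
  keep <- !is.na(mac) & mac >= min_count & ac$n_alleles > 0
  list(matrix = snp_subset(mat, sites = which(keep)), keep = keep)
}

#' Method-of-moments inbreeding coefficient per sample
#'
#' `F = (observed hom - expected hom) / (n sites - expected hom)`, the
#' homozygosity-excess estimator, with the per-site expected homozygosity
#' `1 - 2p(1-p) * n/(n-1)` computed from the panel allele frequencies over
#' `n` called allele copies. Only diploid-coded genotypes of the sample at
#' polymorphic sites enter. Haploid-truth drones genotyped diploid have
#' F near 1; low-F drones indicate unreliable data.
#'
#' @param mat A [snp_matrix()].
#' @param flag_threshold Samples with ploidy 1 and `F` below this value are
#'   flagged for exclusion.
#' @return Tibble: `id`, `population`, `n_sites`, `obs_hom`, `exp_hom`, `F`,
#'   `flagged`.
#' @export
inbreeding_coefficient <- function(mat, flag_threshold = 0.8) {
  ac <- allele_counts(mat)
  p <- ac$alt_freq
  n <- ac$n_alleles
  poly <- !is.na(p) & p > 0 & p < 1 & n > 1
  if (!any(poly)) abort("no polymorphic sites usable for inbreeding F")
  e_hom_site <- 1 - 2 * p * (1 - p) * n / (n - 1)

  res <- purrr::map(seq_len(ncol(mat$geno)), function(j) {
    g <- mat$geno[, j]
    use <- poly & !is.na(g)
    n_sites <- sum(use)
    if (n_sites == 0) {
      return(tibble::tibble(n_sites = 0L, obs_hom = NA_real_,
                            exp_hom = NA_real_, F = NA_real_))
    }
    obs <- sum(g[use] != 1L)
    expd <- sum(e_hom_site[use])
    tibble::tibble(n_sites = n_sites, obs_hom = obs, exp_hom = expd,
                   F = (obs - expd) / (n_sites - expd))
  }) |> purrr::list_rbind()
  out <- dplyr::bind_cols(mat$samples[c("id", "population")], res)
  dplyr::mutate(out, flagged = mat$samples$ploidy == 1L &
                  !is.na(.data$F) & .data$F < flag_threshold)
}

#' Greedy distance-based SNP thinning
#'
#' Left-to-right per chromosome: a site is kept iff its position is at least
#' `min_bp` beyond the last kept position, guaranteeing all retained pairs are
#' `>= min_bp` apart.
#'
#' @param mat A [snp_matrix()].
#' @param min_bp Minimum pairwise distance (default 500).
#' @return A thinned [snp_matrix()].
#' @export
thin_snps <- function(mat, min_bp = 500) {
  keep <- logical(nrow(mat$sites))
  for (chr in unique(mat$sites$chrom)) {
    idx <- which(mat$sites$chrom == chr)
    last <- -Inf
    for (i in idx) {
      if (mat$sites$pos[i] >= last + min_bp) {
        keep[i] <- TRUE
        last <- mat$sites$pos[i]
      }
    }
  }
  snp_subset(mat, sites = which(keep))
}

#' Run the full filter cascade on a VCF
#'
#' Order: hard filters -> site filters (bi-allelic, QUAL, depth,
#' missingness) -> drone-heterozygote handling -> minor allele count.
#' Re-running the cascade on its own output is a no-op.
#'
#' @param vcf A `vcf_data` list from [read_vcf()].
#' @param mac Minimum minor allele count (default 3).
#' @inheritParams apply_site_filters
#' @return List: `matrix` (filtered panel), `log` (removal counts tibble),
#'   `drone_log`.
#' @export
filter_variants <- function(vcf, mac = 3, max_mean_dp = 20, min_qual = 100,
                            max_missing = 0.30) {
  hard <- apply_hard_filters(vcf$info)
  site <- apply_site_filters(vcf, hard_pass = hard$pass,
                             max_mean_dp = max_mean_dp, min_qual = min_qual,
                             max_missing = max_missing)
  has_drones <- any(site$matrix$samples$ploidy == 1L)
  if (has_drones) {
    dr <- handle_drone_heterozygotes(site$matrix)
    m <- dr$matrix
    drone_removed <- dr$log$sites_multi_het_removed
  } else {
    dr <- NULL
    m <- site$matrix
    drone_removed <- 0L
  }
  mf <- mac_filter(m, min_count = mac)
  log <- dplyr::bind_rows(
    site$log,
    tibble::tibble(reason = "drone_multi_het", removed = drone_removed),
    tibble::tibble(reason = "mac", removed = sum(!mf$keep))
  )
  # the MAC-free panel is kept for diversity estimation, where the minor
  # allele count filter would bias pi by excluding rare variants
  list(matrix = mf$matrix, matrix_premac = m, log = log,
       drone_log = if (is.null(dr)) NULL else dr$log)
}
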