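#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration, stage toggles, thresholds and
#' per-stage seeds (derived from the master seed) for [run_pipeline()].
#'
#' @param sim A [sim_config()].
#' @param stages Character vector of stages to run, any of
#'   `"filter"`, `"stats"`, `"centromeres"`, `"peaks"`, `"null"`,
#'   `"ancestry"` (simulation always runs; later stages require earlier ones).
#' @param mac,max_mean_dp,min_qual,max_missing Filter thresholds.
#' @param kinship_threshold Relatedness flag level (default 0.044).
#' @param fst_threshold Per-SNP outlier threshold for the null comparison; if
#'   `NULL`, the empirical 0.998 per-SNP quantile is used.
#' @param thin_bp Thinning distance for the independent-SNP set (default 500).
#' @param null_loci Number of coalescent loci; defaults to the size of the
#'   thinned polymorphic SNP set.
#' @param seed Master seed; stage seeds are derived by fixed offsets.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("filter", "stats", "centromeres",
                                       "peaks", "null", "ancestry"),
                            mac = 3, max_mean_dp = 20, min_qual = 100,
                            max_missing = 0.30, kinship_threshold = 0.044,
                            fst_threshold = NULL, thin_bp = 500,
                            null_loci = NULL, seed = 1L) {
  sim$seed <- as.integer(seed)
  structure(
    list(sim = sim, stages = stages, mac = mac, max_mean_dp = max_mean_dp,
         min_qual = min_qual, max_missing = max_missing,
         kinship_threshold = kinship_threshold, fst_threshold = fst_threshold,
         thin_bp = thin_bp, null_loci = null_loci, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages in dependency order: simulate and write inputs; read and filter the
#' VCF; diversity, kinship and FST statistics; pericentromere detection; peak
#' calling with gene annotation and recombination ratios; the coalescent null
#' and enrichment test; ancestry tracks and correlations. Each stage's
#' headline numbers are aggregated into a report (written as JSON) and every
#' stage is reproducible from the master seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Directory for artifacts and the report.
#' @return List of class `pipeline_report` (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("beescan_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on_stage <- function(s) s %in% config$stages
  skipped <- "skipped"
  report <- list(seed = config$seed, out_dir = out_dir)
  scfg <- config$sim

  stage <- "simulate"
  res <- tryCatch({
    sim <- simulate_study(scfg)
    vcf_path <- file.path(out_dir, "panel.vcf")
    wr <- write_vcf(sim, vcf_path, scfg)
    ref <- generate_reference_and_genes(scfg, out_dir, truth = sim$truth)
    pc <- generate_posteriors_and_clines(sim$truth, scfg)
    readr::write_tsv(pc$posteriors, file.path(out_dir, "posteriors.tsv"))
    readr::write_tsv(pc$clines, file.path(out_dir, "clines.tsv"))
    report$simulate <- list(
      n_snps = nrow(sim$matrix$sites),
      n_samples = nrow(sim$matrix$samples),
      n_selected = length(sim$truth$selected_idx)
    )
    list(sim = sim, wr = wr, ref = ref, pc = pc)
  }, error = function(e) abort(paste0("stage '", stage, "' failed: ", conditionMessage(e))))

  filtered <- NULL
  if (on_stage("filter")) {
    stage <- "filter"
    filtered <- tryCatch({
      vcf <- read_vcf(file.path(out_dir, "panel.vcf"))
      fl <- filter_variants(vcf, mac = config$mac,
                            max_mean_dp = config$max_mean_dp,
                            min_qual = config$min_qual,
                            max_missing = config$max_missing)
      report$filter <- list(
        input_sites = nrow(vcf$matrix$sites),
        retained_sites = nrow(fl$matrix$sites),
        removed = as.list(setNames(fl$log$removed, fl$log$reason))
      )
      fl
    }, error = function(e) abort(paste0("stage '", stage, "' failed: ", conditionMessage(e))))
  } else report$filter <- skipped

  per_snp <- NULL
  windows <- NULL
  if (on_stage("stats") && !is.null(filtered)) {
    stage <- "stats"
    tryCatch({
      paired <- pair_haploids(filtered$matrix_premac, population = "M",
                              seed = config$seed + 11L)
      pis <- purrr::map_dbl(
        setNames(nm = c("A", "C", "M", "lowland", "highland")),
        function(p) {
          pw <- nucleotide_diversity_windows(paired$matrix, population = p,
                                             chrom_lengths = scfg$chrom_lengths)
          attr(pw, "genome_pi")
        }
      )
      theta <- watterson_theta(
        snp_subset(filtered$matrix,
                   samples = which(filtered$matrix$samples$population %in%
                                     c("lowland", "highland"))),
        total_bp = sum(scfg$chrom_lengths)
      )
      kin <- king_kinship(
        snp_subset(filtered$matrix,
                   samples = which(filtered$matrix$samples$population %in%
                                     c("lowland", "highland"))),
        threshold = config$kinship_threshold
      )
      per_snp <- wc_fst_per_snp(filtered$matrix, "lowland", "highland")
      windows <- wc_fst_windowed(per_snp, window_bp = scfg$window_bp,
                                  chrom_lengths = scfg$chrom_lengths)
      readr::write_tsv(tibble::as_tibble(windows), file.path(out_dir, "fst_windows.tsv"))
      report$stats <- list(
        pi = as.list(pis), theta_w = theta$theta_w,
        kinship_max = max(kin$phi, na.rm = TRUE),
        kinship_flagged = sum(kin$flagged)
      )
    }, error = function(e) abort(paste0("stage '", stage, "' failed: ", conditionMessage(e))))
  } else report$stats <- skipped

  centromeres <- NULL
  if (on_stage("centromeres")) {
    stage <- "centromeres"
    tryCatch({
      gw <- gc_windows(res$ref$fasta, window_bp = scfg$window_bp)
      centromeres <- detect_pericentromere(gw)
      if (!is.null(centromeres) && nrow(centromeres) > 0) {
        write_bed(centromeres[c("chrom", "start", "end", "score_gain")],
                  file.path(out_dir, "centromeres.bed"))
      }
      report$centromeres <- list(
        genome_gc = attr(gw, "genome_gc"),
        n_regions = if (is.null(centromeres)) 0L else nrow(centromeres)
      )
    }, error = function(e) abort(paste0("stage '", stage, "' failed: ", conditionMessage(e))))
  } else report$centromeres <- skipped

  if (on_stage("peaks") && !is.null(windows)) {
    stage <- "peaks"
    tryCatch({
      thr <- quantile_thresholds(windows$fst)
      peaks <- call_peaks(windows, thr)
      genes <- annotate_peak_genes(peaks, res$ref$genes)
      peaks2 <- recomb_ratio(peaks, res$ref$recomb)
      if (!is.null(centromeres) && nrow(peaks2) > 0) {
        peaks2 <- flag_pericentromeric(peaks2, centromeres)
      }
      readr::write_tsv(peaks2, file.path(out_dir, "peaks.tsv"))
      report$peaks <- list(
        q998 = thr$q998, q99 = thr$q99, q98 = thr$q98,
        n_peaks = nrow(peaks),
        n_genes = if (is.null(genes)) 0L else dplyr::n_distinct(genes$gene_id),
        mean_recomb_ratio = if (nrow(peaks2) > 0) mean(peaks2$recomb_ratio, na.rm = TRUE) else NA
      )
    }, error = function(e) abort(paste0("stage '", stage, "' failed: ", conditionMessage(e))))
  } else report$peaks <- skipped

  if (on_stage("null") && !is.null(filtered)) {
    stage <- "null"
    tryCatch({
      col <- snp_subset(filtered$matrix,
                        samples = which(filtered$matrix$samples$population %in%
                                          c("lowland", "highland")))
      thin <- thin_snps(col, min_bp = config$thin_bp)
      ac <- allele_counts(thin)
      poly <- !is.na(ac$alt_freq) & ac$alt_count > 0 & ac$alt_count < ac$n_alleles
      thin <- snp_subset(thin, sites = which(poly))
      fst_gw <- reynolds_fst_genomewide(thin, "lowland", "highland")
      T2n <- fst_to_T(max(fst_gw, 0))
      emp <- wc_fst_per_snp(thin, "lowland", "highland")
      threshold <- config$fst_threshold
      if (is.null(threshold)) {
        threshold <- quantile(emp$fst[!is.na(emp$fst)], 0.998, type = 7, names = FALSE)
      }
      n_loci <- if (is.null(config$null_loci)) nrow(thin$sites) else config$null_loci
      model <- split_model(
        n1 = 2 * sum(thin$samples$population == "highland"),
        n2 = 2 * sum(thin$samples$population == "lowland"),
        t_split = T2n / 2, n_loci = n_loci, seed = config$seed + 21L
      )
      null <- simulate_snp_panel(model, threshold = threshold)
      enr <- enrichment_test(emp$fst, null$snps$fst, threshold = threshold)
      readr::write_tsv(enr, file.path(out_dir, "enrichment.tsv"))
      report$null <- list(
        reynolds_fst = fst_gw, T = T2n, t_split_input = T2n / 2,
        threshold = threshold, n_loci = n_loci,
        simulated_mean_fst = null$mean_fst,
        empirical_above = enr$empirical_above,
        simulated_above = enr$simulated_above,
        enrichment_ratio = enr$enrichment_ratio
      )
    }, error = function(e) abort(paste0("stage '", stage, "' failed: ", conditionMessage(e))))
  } else report$null <- skipped

  if (on_stage("ancestry") && !is.null(windows)) {
    stage <- "ancestry"
    tryCatch({
      post <- combine_posterior_A(res$pc$posteriors)
      track <- population_ancestry_track(post)
      sp <- correlate_fst_ancestry(windows, track)
      cl <- correlate_clines(track, res$pc$clines)
      pop_means <- post |>
        dplyr::group_by(.data$population) |>
        dplyr::summarise(mean_pA = mean(.data$pA), .groups = "drop")
      report$ancestry <- list(
        mean_pA = as.list(setNames(pop_means$mean_pA, pop_means$population)),
        mean_delta = mean(track$delta, na.rm = TRUE),
        fst_ancestry_rho = sp$rho, fst_ancestry_p = sp$p,
        cline_r = cl$r, cline_p = cl$p
      )
    }, error = function(e) abort(paste0("stage '", stage, "' failed: ", conditionMessage(e))))
  } else report$ancestry <- skipped

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
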