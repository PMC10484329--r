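#' Empirical quantile thresholds for peak calling
#'
#' Linear-interpolation (type 7) quantiles of the defined window FST values:
#' the 0.998 seed threshold, the 0.99 peak-mean constraint and the 0.98
#' extension threshold.
#'
#' @param window_values Numeric vector of window FST values; NA (undefined
#'   windows) are excluded.
#' @return Tibble: `q998`, `q99`, `q98`, `n_values`.
#' @export
quantile_thresholds <- function(window_values) {
  v <- window_values[!is.na(window_values)]
  if (length(v) == 0) abort("no defined window values")
  q <- quantile(v, c(0.998, 0.99, 0.98), type = 7, names = FALSE)
  tibble::tibble(q998 = q[1], q99 = q[2], q98 = q[3], n_values = length(v))
}

peak_weighted_mean <- function(fst, n_snps) {
  sum(n_snps * fst) / sum(n_snps)
}

#' Call FST outlier peaks from windowed values
#'
#' Seeds are contiguous runs of windows with FST at or above the 0.998
#' quantile (adjacent seed windows merge; gaps are never jumped). Each seed
#' is extended one window at a time, alternating sides starting left: a
#' window is accepted iff its FST is at or above the 0.98 quantile and the
#' extended peak's SNP-count-weighted mean FST stays at or above the 0.99
#' quantile; a side closes on its first rejection. Undefined windows
#' (no SNPs) close a side.
#'
#' @param windows An `fst_windows` tibble from [wc_fst_windowed()].
#' @param thresholds Output of [quantile_thresholds()] (computed from
#'   `windows$fst` when omitted).
#' @return Tibble of class `fst_peaks`: `peak_id`, `chrom`, `start`, `end`,
#'   `n_windows`, `n_snps`, `weighted_mean_fst`, `max_fst`.
#' @export
call_peaks <- function(windows, thresholds = quantile_thresholds(windows$fst)) {
  q998 <- thresholds$q998; q99 <- thresholds$q99; q98 <- thresholds$q98
  peaks <- purrr::map(unique(windows$chrom), function(chr) {
    w <- windows[windows$chrom == chr, ]
    w <- w[order(w$start), ]
    fst <- w$fst
    is_seed <- !is.na(fst) & fst >= q998
    if (!any(is_seed)) return(NULL)
    runs <- rle(is_seed)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1
    seeds <- which(runs$values)

    purrr::map(seeds, function(s) {
      lo <- run_start[s]; hi <- run_end[s]
      accept <- function(i, lo2, hi2) {
        !is.na(fst[i]) && fst[i] >= q98 &&
          peak_weighted_mean(fst[lo2:hi2], w$n_snps[lo2:hi2]) >= q99
      }
      left_open <- TRUE; right_open <- TRUE
      while (left_open || right_open) {
        if (left_open) {
          if (lo > 1 && accept(lo - 1, lo - 1, hi)) lo <- lo - 1 else left_open <- FALSE
        }
        if (right_open) {
          if (hi < nrow(w) && accept(hi + 1, lo, hi + 1)) hi <- hi + 1 else right_open <- FALSE
        }
      }
      tibble::tibble(
        chrom = chr, start = w$start[lo], end = w$end[hi],
        n_windows = hi - lo + 1, n_snps = sum(w$n_snps[lo:hi]),
        weighted_mean_fst = peak_weighted_mean(fst[lo:hi], w$n_snps[lo:hi]),
        max_fst = max(fst[lo:hi], na.rm = TRUE)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (is.null(peaks) || nrow(peaks) == 0) {
    peaks <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      n_windows = integer(), n_snps = integer(),
      weighted_mean_fst = double(), max_fst = double()
    )
  }
  # adjacent seed runs separated only by merged extensions could overlap; keep distinct
  peaks <- dplyr::distinct(peaks) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(peak_id = sprintf("peak_%02d", dplyr::row_number()), .before = 1)
  structure(peaks, thresholds = thresholds, class = c("fst_peaks", class(peaks)))
}

#' Annotate peaks with genes by the exon-overlap rule
#'
#' A gene is assigned to a peak iff at least 30% of its exons overlap the
#' peak by at least 50% of the exon's length. Genes with zero exons are
#' skipped with a warning.
#'
#' @param peaks An `fst_peaks` tibble.
#' @param gene_models Exon tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param min_exon_frac Fraction of the exon that must overlap (default 0.5).
#' @param min_gene_frac Fraction of exons that must qualify (default 0.3).
#' @return Tibble: `peak_id`, `gene_id` (one row per assignment).
#' @export
annotate_peak_genes <- function(peaks, gene_models,
                                min_exon_frac = 0.5, min_gene_frac = 0.3) {
  purrr::map(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, ]
    ex <- gene_models[gene_models$chrom == pk$chrom, ]
    if (nrow(ex) == 0) return(NULL)
    ov <- pmax(0, pmin(ex$end, pk$end) - pmax(ex$start, pk$start) + 1)
    qual <- ov >= min_exon_frac * (ex$end - ex$start + 1)
    per_gene <- tibble::tibble(gene_id = ex$gene_id, qual = qual) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(n_exons = dplyr::n(), n_qual = sum(.data$qual),
                       .groups = "drop")
    hit <- per_gene$n_qual / per_gene$n_exons >= min_gene_frac
    if (!any(hit)) return(NULL)
    tibble::tibble(peak_id = pk$peak_id, gene_id = per_gene$gene_id[hit])
  }) |> purrr::list_rbind()
}

#' Gene-wise FST as a ratio of sums over the gene span
#'
#' The gene span is the transcript bound (first exon start to last exon end,
#' introns included); the gene value is the sum of per-SNP Weir-Cockerham
#' numerators over denominators for SNPs inside the span. Genes with no SNPs
#' (or zero denominator) are NA.
#'
#' @param per_snp Output of [wc_fst_per_snp()].
#' @param gene_models Exon tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `n_snps`, `fst`.
#' @export
genewise_fst <- function(per_snp, gene_models) {
  spans <- gene_models |>
    dplyr::group_by(.data$gene_id, .data$chrom) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  ok <- !is.na(per_snp$num) & !is.na(per_snp$den)
  purrr::map(seq_len(nrow(spans)), function(i) {
    g <- spans[i, ]
    inside <- ok & per_snp$chrom == g$chrom &
      per_snp$pos >= g$start & per_snp$pos <= g$end
    den <- sum(per_snp$den[inside])
    tibble::tibble(
      gene_id = g$gene_id, chrom = g$chrom, start = g$start, end = g$end,
      n_snps = sum(inside),
      fst = if (sum(inside) > 0 && den > 0) sum(per_snp$num[inside]) / den else NA_real_
    )
  }) |> purrr::list_rbind()
}

#' Hypergeometric gene-set enrichment with FDR correction
#'
#' Per term, the upper-tail hypergeometric probability `P(X >= k)` of drawing
#' `k` foreground members of the term given `N` background genes, `K` term
#' members and `n` foreground genes; Benjamini-Hochberg correction across
#' terms.
#'
#' @param foreground_ids Character vector (must be a subset of background).
#' @param background_ids Character vector.
#' @param term_sets Tibble (`term`, `gene_id`).
#' @param alpha FDR significance cutoff (default 0.05).
#' @return Tibble: `term`, `K`, `k`, `p`, `q`, `significant`, sorted by `p`.
#' @export
hypergeom_enrichment <- function(foreground_ids, background_ids, term_sets,
                                 alpha = 0.05) {
  foreground_ids <- unique(foreground_ids)
  background_ids <- unique(background_ids)
  if (!all(foreground_ids %in% background_ids)) {
    abort("foreground must be a subset of background")
  }
  N <- length(background_ids)
  n <- length(foreground_ids)
  res <- term_sets |>
    dplyr::filter(.data$gene_id %in% background_ids) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = dplyr::n_distinct(intersect(.data$gene_id, foreground_ids)),
      .groups = "drop"
    ) |>
    dplyr::mutate(p = phyper(.data$k - 1, .data$K, N - .data$K, n,
                             lower.tail = FALSE))
  res |>
    dplyr::mutate(q = p.adjust(.data$p, method = "BH"),
                  significant = .data$q < alpha) |>
    dplyr::arrange(.data$p)
}

#' Recombination-rate ratio of peaks to their chromosome average
#'
#' Length-weighted mean rate of the map intervals inside each peak, divided
#' by the length-weighted chromosome mean.
#'
#' @param peaks An `fst_peaks` tibble (or any tibble with `peak_id`, `chrom`,
#'   `start`, `end`).
#' @param recomb_map Tibble (`chrom`, `start`, `end`, `rate`), 1-based
#'   inclusive.
#' @return Peaks with `peak_rate`, `chrom_rate`, `recomb_ratio` columns.
#' @export
recomb_ratio <- function(peaks, recomb_map) {
  chrom_mean <- recomb_map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      chrom_rate = sum(.data$rate * (.data$end - .data$start + 1)) /
        sum(.data$end - .data$start + 1),
      .groups = "drop"
    )
  rates <- purrr::map_dbl(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, ]
    m <- recomb_map[recomb_map$chrom == pk$chrom, ]
    ov <- pmax(0, pmin(m$end, pk$end) - pmax(m$start, pk$start) + 1)
    if (sum(ov) == 0) return(NA_real_)
    sum(m$rate * ov) / sum(ov)
  })
  peaks |>
    tibble::as_tibble() |>
    dplyr::mutate(peak_rate = rates) |>
    dplyr::left_join(chrom_mean, by = "chrom") |>
    dplyr::mutate(recomb_ratio = .data$peak_rate / .data$chrom_rate)
}

#' Flag peaks overlapping detected pericentromeric regions
#'
#' @param peaks An `fst_peaks` tibble.
#' @param centromeres Output of [detect_pericentromere()].
#' @return Peaks with a logical `pericentromeric` column.
#' @export
flag_pericentromeric <- function(peaks, centromeres) {
  flag <- purrr::map_lgl(seq_len(nrow(peaks)), function(i) {
    pk <- peaks[i, ]
    any(centromeres$chrom == pk$chrom &
          centromeres$start <= pk$end & centromeres$end >= pk$start)
  })
  dplyr::mutate(tibble::as_tibble(peaks), pericentromeric = flag)
}
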