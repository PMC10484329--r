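#' GC content in non-overlapping windows, with cumulative low-GC scores
#'
#' GC fraction per window excludes N bases from numerator and denominator;
#' all-N windows are undefined. The genome-wide mean is computed over all
#' called bases. Each window scores +1 when its GC is below the genome mean,
#' -1 when above, 0 when equal or undefined.
#'
#' @param fasta Path to a FASTA file, or a `Biostrings::DNAStringSet`.
#' @param window_bp Window size (default 10 kbp).
#' @return Tibble of class `gc_windows`: `chrom`, `index` (0-based), `start`,
#'   `end`, `gc`, `score`, `cum` (per-chromosome cumulative score); genome
#'   mean GC in `attr(, "genome_gc")`.
#' @export
gc_windows <- function(fasta, window_bp = 10000) {
  dna <- if (inherits(fasta, "DNAStringSet")) fasta else Biostrings::readDNAStringSet(fasta)
  if (length(dna) == 0) abort("empty FASTA")

  per_chrom <- purrr::imap(as.list(dna), function(seq, chr) {
    len <- length(seq)
    starts <- seq(1, len, by = window_bp)
    ends <- pmin(starts + window_bp - 1, len)
    v <- Biostrings::Views(seq, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "A", "T"))
    gc_bases <- freq[, "G"] + freq[, "C"]
    called <- rowSums(freq)
    tibble::tibble(
      chrom = chr, index = seq_along(starts) - 1L, start = starts, end = ends,
      gc_bases = gc_bases, called = called,
      gc = ifelse(called > 0, gc_bases / called, NA_real_)
    )
  }) |> purrr::list_rbind()

  genome_gc <- sum(per_chrom$gc_bases) / sum(per_chrom$called)
  out <- per_chrom |>
    dplyr::mutate(
      score = dplyr::case_when(
        is.na(.data$gc) ~ 0L,
        .data$gc < genome_gc ~ 1L,
        .data$gc > genome_gc ~ -1L,
        TRUE ~ 0L
      )
    ) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(cum = cumsum(.data$score)) |>
    dplyr::ungroup() |>
    dplyr::select(-"gc_bases", -"called")
  structure(out, genome_gc = genome_gc, class = c("gc_windows", class(out)))
}

#' Cumulative low-GC score track
#'
#' Per chromosome, the track starts at 0 and adds each window's score left to
#' right (prefix sums of the +1/0/-1 scores).
#'
#' @param windows A `gc_windows` tibble (or any tibble with `chrom`, `score`).
#' @return The input with a `cum` column (recomputed).
#' @export
cumulative_scores <- function(windows) {
  windows |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(cum = cumsum(.data$score)) |>
    dplyr::ungroup()
}

#' Detect the pericentromeric region of each chromosome
#'
#' Seed: the contiguous `span_windows`-window span (0.5 Mb at 10 kbp) with the
#' highest net score sum, ties broken leftmost; chromosomes whose best span
#' has non-positive gain, or with fewer than `span_windows` windows, yield no
#' region. The seed is extended in each direction by `block_windows`-window
#' blocks while the block's net score is at least `block_min_gain` (partial
#' blocks at chromosome edges are not absorbed), then by single windows while
#' the adjacent window's score is +1.
#'
#' @param windows A `gc_windows` tibble from [gc_windows()].
#' @param span_windows Seed span length in windows (default 50).
#' @param block_windows Block-extension size (default 10).
#' @param block_min_gain Minimum net score of an accepted block (default 5).
#' @return Tibble: `chrom`, `start_window`, `end_window` (0-based ordinals),
#'   `start`, `end` (bp), `score_gain`. Chromosomes without a region are
#'   absent.
#' @export
detect_pericentromere <- function(windows, span_windows = 50,
                                  block_windows = 10, block_min_gain = 5) {
  purrr::map(unique(windows$chrom), function(chr) {
    w <- windows[windows$chrom == chr, ]
    k <- nrow(w)
    if (k < span_windows) return(NULL)
    score <- w$score
    cum <- cumsum(score)
    # net gain of span ending at e (1-based), length span_windows
    ends <- span_windows:k
    gains <- cum[ends] - c(0, cum)[ends - span_windows + 1]
    best <- which.max(gains) # ties -> leftmost
    if (gains[best] <= 0) return(NULL)
    lo <- ends[best] - span_windows + 1
    hi <- ends[best]

    repeat {
      ext <- FALSE
      if (lo - block_windows >= 1 &&
          sum(score[(lo - block_windows):(lo - 1)]) >= block_min_gain) {
        lo <- lo - block_windows; ext <- TRUE
      }
      if (hi + block_windows <= k &&
          sum(score[(hi + 1):(hi + block_windows)]) >= block_min_gain) {
        hi <- hi + block_windows; ext <- TRUE
      }
      if (!ext) break
    }
    while (lo > 1 && score[lo - 1] == 1L) lo <- lo - 1
    while (hi < k && score[hi + 1] == 1L) hi <- hi + 1

    tibble::tibble(
      chrom = chr,
      start_window = w$index[lo], end_window = w$index[hi],
      start = w$start[lo], end = w$end[hi],
      score_gain = sum(score[lo:hi])
    )
  }) |> purrr::list_rbind()
}

#' Write genomic intervals as BED (0-based half-open)
#'
#' @param x Tibble with `chrom`, `start`, `end` (1-based inclusive) and
#'   optional further columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  bed <- dplyr::mutate(x, start = .data$start - 1L)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED / bedGraph-like file back to 1-based inclusive intervals
#'
#' @param path BED path.
#' @param col_names Names for the columns (first three are chrom/start/end).
#' @return Tibble with 1-based inclusive `start`.
#' @export
read_bed <- function(path, col_names = c("chrom", "start", "end", "value")) {
  n_col <- ncol(readr::read_tsv(path, col_names = FALSE, n_max = 1,
                                show_col_types = FALSE))
  x <- readr::read_tsv(path, col_names = col_names[seq_len(n_col)],
                       show_col_types = FALSE)
  dplyr::mutate(x, start = .data$start + 1L)
}
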