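# Independent brute-force oracles. These deliberately re-derive each
# algorithm in the most literal way possible and stay unvectorised.

# Weir & Cockerham (1984) two-population diploid estimator, transcribed
# genotype-by-genotype from the variance-component definitions.
oracle_wc_fst_site <- function(g1, g2) {
  # g1, g2: integer dosage vectors (0/1/2, NA allowed) for the two samples
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  r <- 2
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) return(c(a = NA_real_, d = NA_real_))
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  n_bar <- mean(c(n1, n2))
  n_c <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  c(a = a, d = a + b + cc)
}

# exhaustive peak caller: enumerate seed runs and simulate the alternating
# extension procedure window by window
oracle_call_peaks <- function(fst, n_snps, q998, q99, q98) {
  k <- length(fst)
  seed_flag <- !is.na(fst) & fst >= q998
  peaks <- list()
  i <- 1
  while (i <= k) {
    if (!seed_flag[i]) { i <- i + 1; next }
    j <- i
    while (j < k && seed_flag[j + 1]) j <- j + 1
    lo <- i; hi <- j
    wmean <- function(lo2, hi2) {
      sum(n_snps[lo2:hi2] * fst[lo2:hi2]) / sum(n_snps[lo2:hi2])
    }
    left_open <- TRUE; right_open <- TRUE
    repeat {
      if (!left_open && !right_open) break
      if (left_open) {
        cand <- lo - 1
        if (cand >= 1 && !is.na(fst[cand]) && fst[cand] >= q98 &&
            wmean(cand, hi) >= q99) lo <- cand else left_open <- FALSE
      }
      if (right_open) {
        cand <- hi + 1
        if (cand <= k && !is.na(fst[cand]) && fst[cand] >= q98 &&
            wmean(lo, cand) >= q99) hi <- cand else right_open <- FALSE
      }
    }
    peaks[[length(peaks) + 1]] <- c(lo = lo, hi = hi)
    i <- j + 1
  }
  peaks
}

# exhaustive pericentromere detector: try every 50-window span, then simulate
# the block and single-window extensions step by step
oracle_centromere <- function(score, span = 50, block = 10, gain = 5) {
  k <- length(score)
  if (k < span) return(NULL)
  best_gain <- -Inf; best_lo <- NA
  for (lo in 1:(k - span + 1)) {
    g <- sum(score[lo:(lo + span - 1)])
    if (g > best_gain) { best_gain <- g; best_lo <- lo }
  }
  if (best_gain <= 0) return(NULL)
  lo <- best_lo; hi <- best_lo + span - 1
  repeat {
    moved <- FALSE
    if (lo - block >= 1 && sum(score[(lo - block):(lo - 1)]) >= gain) {
      lo <- lo - block; moved <- TRUE
    }
    if (hi + block <= k && sum(score[(hi + 1):(hi + block)]) >= gain) {
      hi <- hi + block; moved <- TRUE
    }
    if (!moved) break
  }
  while (lo > 1 && score[lo - 1] == 1) lo <- lo - 1
  while (hi < k && score[hi + 1] == 1) hi <- hi + 1
  c(lo = lo, hi = hi)
}

# dependent-correlation z: second, independent transcription of Dunn &
# Clark's z with the backtransformed average Fisher Z
oracle_dependent_z <- function(r_jk, r_jh, r_kh, n) {
  fisher_z <- function(r) 0.5 * log((1 + r) / (1 - r))
  inv_z <- function(z) (exp(2 * z) - 1) / (exp(2 * z) + 1)
  zjk <- fisher_z(r_jk); zjh <- fisher_z(r_jh)
  rm_ <- inv_z((zjk + zjh) / 2)
  num <- r_kh * (1 - rm_^2 - rm_^2) - 0.5 * rm_^2 * (1 - rm_^2 - rm_^2 - r_kh^2)
  cov_ <- num / (1 - rm_^2)^2
  (zjk - zjh) * sqrt((n - 3) / (2 - 2 * cov_))
}

# windowed gc_windows built from a character vector genome
oracle_gc_windows_tbl <- function(scores_by_chrom) {
  purrr::imap(scores_by_chrom, function(sc, chr) {
    tibble::tibble(
      chrom = chr, index = seq_along(sc) - 1L,
      start = (seq_along(sc) - 1L) * 10000L + 1L,
      end = seq_along(sc) * 10000L,
      gc = NA_real_, score = as.integer(sc), cum = cumsum(as.integer(sc))
    )
  }) |> purrr::list_rbind()
}
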