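#' Reduce 6-state diplotype posteriors to per-lineage ancestry probabilities
#'
#' `p(A) = p(AA) + (p(MA) + p(CA))/2`, and analogously
#' `p(C) = p(CC) + (p(CM) + p(CA))/2`, `p(M) = p(MM) + (p(CM) + p(MA))/2`,
#' so the three sum to 1.
#'
#' @param posteriors Tibble with columns `pCC`, `pCM`, `pCA`, `pMM`, `pMA`,
#'   `pAA` (one row per SNP x individual).
#' @param tol Tolerance for each row's probabilities summing to 1.
#' @return The input with `pA`, `pC`, `pM` columns added.
#' @export
combine_posterior_A <- function(posteriors, tol = 1e-6) {
  cols <- paste0("p", diplotype_states)
  if (!all(cols %in% names(posteriors))) {
    abort("posterior table must have columns pCC, pCM, pCA, pMM, pMA, pAA")
  }
  s <- rowSums(posteriors[cols])
  if (any(abs(s - 1) > tol)) {
    abort(sprintf("posterior row %d does not sum to 1", which(abs(s - 1) > tol)[1]))
  }
  dplyr::mutate(
    posteriors,
    pA = .data$pAA + (.data$pMA + .data$pCA) / 2,
    pC = .data$pCC + (.data$pCM + .data$pCA) / 2,
    pM = .data$pMM + (.data$pCM + .data$pMA) / 2
  )
}

#' Per-SNP mean A-ancestry per population and the lowland-highland difference
#'
#' @param posteriors Posterior tibble (with `pA`, else it is computed via
#'   [combine_posterior_A()]); needs `snp_id`, `chrom`, `pos`, `sample`,
#'   `population`.
#' @param lowland,highland Population labels entering the difference
#'   `delta = pA(lowland) - pA(highland)`.
#' @return Tibble of class `ancestry_track`: `snp_id`, `chrom`, `pos`, one
#'   `pA_<population>` column per population, `delta`.
#' @export
population_ancestry_track <- function(posteriors, lowland = "lowland",
                                      highland = "highland") {
  if (!"pA" %in% names(posteriors)) posteriors <- combine_posterior_A(posteriors)
  pops <- unique(posteriors$population)
  if (!all(c(lowland, highland) %in% pops)) abort("empty or missing population")
  track <- posteriors |>
    dplyr::group_by(.data$snp_id, .data$chrom, .data$pos, .data$population) |>
    dplyr::summarise(pA = mean(.data$pA), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "population", values_from = "pA",
                       names_prefix = "pA_") |>
    dplyr::arrange(.data$chrom, .data$pos)
  track$delta <- track[[paste0("pA_", lowland)]] - track[[paste0("pA_", highland)]]
  structure(track, class = c("ancestry_track", class(track)))
}

#' Spearman correlation between windowed FST and the ancestry difference
#'
#' The per-SNP ancestry difference is averaged within each FST window, then
#' rank-correlated (tie-corrected) with the window FST values.
#'
#' @param windows An `fst_windows` tibble.
#' @param track An `ancestry_track` tibble.
#' @return Tibble: `rho`, `p`, `n`, `method`.
#' @export
correlate_fst_ancestry <- function(windows, track) {
  win_delta <- purrr::map(unique(windows$chrom), function(chr) {
    w <- windows[windows$chrom == chr, ]
    tr <- track[track$chrom == chr, ]
    idx <- findInterval(tr$pos, w$start)
    agg <- tapply(tr$delta, idx, mean)
    w$delta <- NA_real_
    w$delta[as.integer(names(agg))] <- agg
    w
  }) |> purrr::list_rbind()
  use <- !is.na(win_delta$fst) & !is.na(win_delta$delta)
  if (sum(use) < 3) abort("fewer than 3 paired windows")
  ct <- suppressWarnings(
    cor.test(win_delta$fst[use], win_delta$delta[use], method = "spearman",
             exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = sum(use),
                 method = "spearman")
}

#' Pearson correlation between the ancestry difference and cline steepness
#'
#' @param track An `ancestry_track` tibble.
#' @param clines Tibble (`snp_id`, `steepness`).
#' @return Tibble: `r`, `p`, `n`, `method`.
#' @export
correlate_clines <- function(track, clines) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(track)[c("snp_id", "delta")],
    clines[c("snp_id", "steepness")],
    by = "snp_id"
  )
  joined <- joined[complete.cases(joined), ]
  if (nrow(joined) == 0) abort("no SNPs shared between track and cline table")
  ct <- cor.test(joined$delta, joined$steepness, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = nrow(joined),
                 method = "pearson")
}

#' Compare two overlapping dependent correlations
#'
#' Dunn & Clark's z with the backtransformed-average Fisher Z modification of
#' Hittner, May & Silver (2003), for correlations `r_jk` and `r_jh` sharing
#' variable `j`, with `r_kh` the correlation of the non-shared variables and
#' `n` the number of paired observations. Two-sided p from the standard
#' normal.
#'
#' @param r_jk,r_jh The two correlations being compared.
#' @param r_kh Correlation between the non-shared variables.
#' @param n Sample size (>= 4).
#' @return List of class `cor_comparison`: inputs plus `z` and `p`.
#' @export
compare_dependent_correlations <- function(r_jk, r_jh, r_kh, n) {
  if (n < 4) abort("n must be at least 4")
  rs <- c(r_jk, r_jh, r_kh)
  if (any(abs(rs) > 1)) abort("correlations must lie in [-1, 1]")
  if (any(abs(c(r_jk, r_jh)) == 1)) abort("degenerate correlation of magnitude 1")
  z1 <- atanh(r_jk)
  z2 <- atanh(r_jh)
  rm_ <- tanh((z1 + z2) / 2) # backtransformed average
  cov_num <- r_kh * (1 - 2 * rm_^2) - 0.5 * rm_^2 * (1 - 2 * rm_^2 - r_kh^2)
  c_ <- cov_num / (1 - rm_^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * c_))
  p <- 2 * pnorm(-abs(z))
  structure(
    list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n, z = z, p = p),
    class = "cor_comparison"
  )
}

#' @export
print.cor_comparison <- function(x, ...) {
  cat(sprintf(
    "<cor_comparison> r_jk=%.3f vs r_jh=%.3f (r_kh=%.3f, n=%d): z=%.3f, p=%.4g\n",
    x$r_jk, x$r_jh, x$r_kh, x$n, x$z, x$p
  ))
  invisible(x)
}

#' @export
tidy.cor_comparison <- function(x, ...) {
  tibble::tibble(r_jk = x$r_jk, r_jh = x$r_jh, r_kh = x$r_kh, n = x$n,
                 z = x$z, p = x$p)
}

#' @export
glance.cor_comparison <- function(x, ...) tidy(x)

#' Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
#'
#' Sums, over all tables with the observed margins, the probabilities that do
#' not exceed the observed table's probability (with a small relative
#' tolerance for float ties).
#'
#' @param tbl 2x2 matrix of counts.
#' @return p-value.
#' @export
fisher_exact_two_sided <- function(tbl) {
  stopifnot(is.matrix(tbl), all(dim(tbl) == 2), all(tbl >= 0))
  m <- sum(tbl[1, ]); n_ <- sum(tbl[2, ]); k <- sum(tbl[, 1])
  support <- max(0, k - n_):min(k, m)
  dens <- stats::dhyper(support, m, n_, k)
  obs <- stats::dhyper(tbl[1, 1], m, n_, k)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

#' Classify external populations by ancestry level and test the association
#' with significantly higher highland correlation
#'
#' Each external population is classed by its genome-wide A ancestry: below
#' the highland level, or between the highland and lowland levels
#' (populations outside both classes are excluded and logged). The 2x2 table
#' of class against "significantly higher correlation with the highland
#' population" (z > 0 and p below `alpha`) is tested with the two-sided
#' Fisher exact test.
#'
#' @param comparisons Tibble with one row per external population: columns
#'   `population`, `A_level`, `z` (positive when the highland correlation is
#'   the larger), `p`.
#' @param hl_level,ll_level Genome-wide A-ancestry of the highland and
#'   lowland focal populations (defaults 0.686 and 0.847).
#' @param alpha Significance cutoff for "significantly higher" (default
#'   0.001).
#' @return List of class `ancestry_classification`: `table` (2x2), `p`
#'   (Fisher two-sided), `excluded` (character), `comparisons` (with class
#'   and significance columns).
#' @export
classify_and_test <- function(comparisons, hl_level = 0.686, ll_level = 0.847,
                              alpha = 0.001) {
  cls <- dplyr::case_when(
    comparisons$A_level < hl_level ~ "below_highland",
    comparisons$A_level < ll_level ~ "between",
    TRUE ~ NA_character_
  )
  excluded <- comparisons$population[is.na(cls)]
  keep <- !is.na(cls)
  sig <- comparisons$z > 0 & comparisons$p < alpha
  tbl <- matrix(
    c(sum(cls[keep] == "below_highland" & sig[keep]),
      sum(cls[keep] == "below_highland" & !sig[keep]),
      sum(cls[keep] == "between" & sig[keep]),
      sum(cls[keep] == "between" & !sig[keep])),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("below_highland", "between"),
                    c("sig_higher_highland", "not"))
  )
  structure(
    list(
      table = tbl, p = fisher_exact_two_sided(tbl), excluded = excluded,
      comparisons = dplyr::mutate(comparisons, class = cls,
                                  sig_higher_highland = sig)
    ),
    class = "ancestry_classification"
  )
}

#' @export
print.ancestry_classification <- function(x, ...) {
  print(x$table)
  cat(sprintf("Fisher exact two-sided p = %.4g\n", x$p))
  if (length(x$excluded)) {
    cat("excluded populations:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.ancestry_classification <- function(x, ...) {
  tibble::tibble(
    n_below_sig = x$table[1, 1], n_below = sum(x$table[1, ]),
    n_between_sig = x$table[2, 1], n_between = sum(x$table[2, ]),
    p = x$p
  )
}
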