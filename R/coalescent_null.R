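#' Convert FST to the scaled split time T
#'
#' `T = -ln(1 - FST) / 2`, in units of 2N generations; the inverse
#' `1 - exp(-2T)` recovers FST. The coalescent simulator measures time in 4N
#' units, so its split-time input is `T / 2`.
#'
#' @param fst FST in `[0, 1)`.
#' @return T.
#' @export
fst_to_T <- function(fst) {
  if (any(fst < 0 | fst >= 1)) abort("fst must lie in [0, 1)")
  -log(1 - fst) / 2
}

#' Scale a per-bp mutation rate to a locus
#'
#' @param locus_bp Locus length in bp.
#' @param theta_per_bp Population mutation rate per bp.
#' @return `locus_bp * theta_per_bp`.
#' @export
scale_theta <- function(locus_bp, theta_per_bp) {
  if (locus_bp < 0 || theta_per_bp < 0) abort("both arguments must be non-negative")
  locus_bp * theta_per_bp
}

#' Two-deme split model for the coalescent null
#'
#' An ancestral population splits into two demes of unchanged, constant and
#' equal size with no subsequent gene flow. Defaults are the study design:
#' 28 + 30 sampled copies, split at 0.0150 in 4N-generation units (half the
#' 2N-unit T of 0.0301), a 906-bp locus at theta 4.23, and one exported
#' bi-allelic SNP per locus for 248,598 loci. With a single fixed segregating
#' site the locus theta does not affect the exported SNP's distribution; it
#' is carried for interface parity.
#'
#' @param n1,n2 Sampled allele copies per deme.
#' @param t_split Split time in 4N-generation units.
#' @param theta_locus Scaled locus mutation rate.
#' @param n_loci Number of independent loci (one SNP each).
#' @param seed Integer seed.
#' @return List of class `split_model`.
#' @export
split_model <- function(n1 = 28, n2 = 30, t_split = 0.0150,
                        theta_locus = 4.23, n_loci = 248598, seed = 1L) {
  if (n1 < 2 || n2 < 2) abort("n1 and n2 must be at least 2")
  if (t_split < 0) abort("t_split must be non-negative")
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2), t_split = t_split,
         theta_locus = theta_locus, n_loci = as.integer(n_loci),
         seed = as.integer(seed)),
    class = "split_model"
  )
}

#' Simulate one genealogy under the split model
#'
#' Reference R implementation (one locus at a time) of the process the
#' compiled panel simulator runs: within-deme coalescence at rate `k(k-1)`
#' per 4N-unit time until the split, then panmictic coalescence of the merged
#' lineages. Returns every non-root branch with its length and the number of
#' descendant tips per deme.
#'
#' @param model A [split_model()].
#' @return List: `branches` (tibble `length`, `d1`, `d2`), `tmrca`.
#' @export
simulate_genealogy <- function(model) {
  n <- model$n1 + model$n2
  deme <- c(rep(1L, model$n1), rep(2L, model$n2))
  d1 <- as.integer(deme == 1L)
  d2 <- as.integer(deme == 2L)
  birth <- numeric(n)
  branches <- list()
  t <- 0
  merged <- model$t_split <= 0
  while (length(deme) > 1) {
    k1 <- sum(deme == 1L); k2 <- sum(deme == 2L)
    rates <- if (merged) c(length(deme) * (length(deme) - 1), 0) else
      c(k1 * (k1 - 1), k2 * (k2 - 1))
    total <- sum(rates)
    if (!merged && total == 0) {
      t <- model$t_split; merged <- TRUE; deme[] <- 1L
      next
    }
    dt <- stats::rexp(1, total)
    if (!merged && t + dt >= model$t_split) {
      t <- model$t_split; merged <- TRUE; deme[] <- 1L
      next
    }
    t <- t + dt
    target <- if (merged || runif(1) * total < rates[1]) 1L else 2L
    in_target <- if (merged) seq_along(deme) else which(deme == target)
    pair <- sample(in_target, 2)
    for (i in pair) {
      branches[[length(branches) + 1]] <-
        c(length = t - birth[i], d1 = d1[i], d2 = d2[i])
    }
    a <- pair[1]; b <- pair[2]
    d1[a] <- d1[a] + d1[b]; d2[a] <- d2[a] + d2[b]
    birth[a] <- t
    deme <- deme[-b]; d1 <- d1[-b]; d2 <- d2[-b]; birth <- birth[-b]
  }
  branches <- tibble::as_tibble(do.call(rbind, branches))
  list(branches = branches, tmrca = t)
}

#' Place a single mutation uniformly on a genealogy
#'
#' The mutated branch is drawn proportional to branch length; the derived
#' allele is carried by that branch's descendants, so every exported SNP
#' segregates in the total sample.
#'
#' @param genealogy Output of [simulate_genealogy()].
#' @return Tibble: `d1`, `d2` (derived copies per deme).
#' @export
drop_single_mutation <- function(genealogy) {
  br <- genealogy$branches
  total <- sum(br$length)
  if (total <= 0) abort("genealogy has no branch length")
  hit <- sample.int(nrow(br), 1, prob = br$length)
  tibble::tibble(d1 = br$d1[hit], d2 = br$d2[hit])
}

#' Per-SNP Weir-Cockerham FST from haploid derived-allele counts
#'
#' @param d1,d2 Derived copies per deme.
#' @param n1,n2 Sampled copies per deme.
#' @return Numeric FST vector (NA where the denominator is zero).
#' @export
fst_from_counts <- function(d1, d2, n1, n2) {
  comp <- wc_components_haploid(rep(n1, length(d1)), d1 / n1,
                                rep(n2, length(d2)), d2 / n2)
  ifelse(comp$den != 0, comp$num / comp$den, NA_real_)
}

#' Simulate the full SNP panel under the split null
#'
#' Runs `n_loci` independent genealogies (compiled path), exports one
#' segregating SNP each, and computes per-SNP Weir-Cockerham FST on the
#' haploid counts.
#'
#' @param model A [split_model()].
#' @param threshold FST threshold for the outlier count (default 0.255, the
#'   0.998 quantile of the matched empirical per-SNP distribution).
#' @param use_compiled Use the C++ panel simulator (default); the pure-R path
#'   exists for cross-checking.
#' @return List of class `coalescent_null`: `snps` (tibble `d1`, `d2`,
#'   `fst`), `model`, `threshold`, `mean_fst`, `n_above`.
#' @export
simulate_snp_panel <- function(model, threshold = 0.255, use_compiled = TRUE) {
  set.seed(model$seed)
  if (use_compiled) {
    counts <- sim_split_snps_cpp(model$n1, model$n2, model$t_split, model$n_loci)
    snps <- tibble::tibble(d1 = counts[, 1], d2 = counts[, 2])
  } else {
    snps <- purrr::map(seq_len(model$n_loci), function(i) {
      drop_single_mutation(simulate_genealogy(model))
    }) |> purrr::list_rbind()
  }
  snps$fst <- fst_from_counts(snps$d1, snps$d2, model$n1, model$n2)
  comp <- wc_components_haploid(rep(model$n1, nrow(snps)), snps$d1 / model$n1,
                                rep(model$n2, nrow(snps)), snps$d2 / model$n2)
  structure(
    list(
      snps = snps, model = model, threshold = threshold,
      mean_fst = mean(snps$fst, na.rm = TRUE),
      # dataset-average conventions: ratio of sums, and the mean over SNPs
      # with positive estimates (non-positive per-SNP values are discarded
      # in the usual per-site outlier workflow)
      weighted_fst = sum(comp$num) / sum(comp$den),
      mean_fst_positive = mean(snps$fst[snps$fst > 0], na.rm = TRUE),
      n_above = sum(snps$fst > threshold, na.rm = TRUE)
    ),
    class = "coalescent_null"
  )
}

#' @export
print.coalescent_null <- function(x, ...) {
  cat(sprintf(
    "<coalescent_null> %d loci, n1=%d n2=%d, t_split=%.4f (4N units)\n",
    x$model$n_loci, x$model$n1, x$model$n2, x$model$t_split
  ))
  cat(sprintf("mean per-SNP FST = %.4f; %d SNPs with FST > %.3f\n",
              x$mean_fst, x$n_above, x$threshold))
  invisible(x)
}

#' @export
tidy.coalescent_null <- function(x, ...) x$snps

#' @export
glance.coalescent_null <- function(x, ...) {
  tibble::tibble(
    n_loci = x$model$n_loci, t_split = x$model$t_split,
    mean_fst = x$mean_fst, mean_fst_positive = x$mean_fst_positive,
    weighted_fst = x$weighted_fst, threshold = x$threshold, n_above = x$n_above
  )
}

#' Enrichment of highly divergent SNPs over the neutral null
#'
#' Counts SNPs above the threshold in the empirical and simulated per-SNP FST
#' distributions; the enrichment ratio compares the two counts after scaling
#' to equal totals.
#'
#' @param empirical_fst,simulated_fst Numeric vectors of per-SNP FST.
#' @param threshold FST cutoff (default 0.255).
#' @return Tibble: counts, totals, means, `enrichment_ratio`.
#' @export
enrichment_test <- function(empirical_fst, simulated_fst, threshold = 0.255) {
  if (length(empirical_fst) == 0 || length(simulated_fst) == 0) {
    abort("both FST distributions must be non-empty")
  }
  emp_n <- sum(!is.na(empirical_fst))
  sim_n <- sum(!is.na(simulated_fst))
  emp_k <- sum(empirical_fst > threshold, na.rm = TRUE)
  sim_k <- sum(simulated_fst > threshold, na.rm = TRUE)
  tibble::tibble(
    threshold = threshold,
    empirical_total = emp_n, simulated_total = sim_n,
    empirical_above = emp_k, simulated_above = sim_k,
    empirical_mean = mean(empirical_fst, na.rm = TRUE),
    simulated_mean = mean(simulated_fst, na.rm = TRUE),
    enrichment_ratio = (emp_k / emp_n) / (sim_k / sim_n)
  )
}
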