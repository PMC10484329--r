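#include <Rcpp.h>
using namespace Rcpp;

// Two-deme split coalescent with exactly one segregating mutation per locus.
//
// Time is measured in units of 4N generations (the ms convention): with k
// lineages in a deme of relative size 1, the total coalescence rate is
// k*(k-1) per unit time.  Two demes coalesce independently until t_split,
// after which all remaining lineages merge into one panmictic ancestral
// population.  One mutation is then placed uniformly at random along the
// total (non-root) branch length, so every exported SNP segregates.
//
// Uses R's RNG (RNGScope), so results are reproducible under set.seed().

// [[Rcpp::export]]
IntegerMatrix sim_split_snps_cpp(int n1, int n2, double t_split, int n_loci) {
  if (n1 < 2 || n2 < 2) stop("need at least two sampled copies per deme");
  if (t_split < 0) stop("t_split must be non-negative");
  if (n_loci < 1) stop("n_loci must be positive");

  const int n = n1 + n2;
  IntegerMatrix out(n_loci, 2);

  // active lineage state
  std::vector<int> deme(n), d1(n), d2(n);
  std::vector<double> birth(n);
  // finalized branches: length and descendant counts
  std::vector<double> blen(2 * n);
  std::vector<int> b1(2 * n), b2(2 * n);

  for (int locus = 0; locus < n_loci; ++locus) {
    int k = n, nb = 0;
    for (int i = 0; i < n; ++i) {
      deme[i] = (i < n1) ? 1 : 2;
      d1[i] = (i < n1) ? 1 : 0;
      d2[i] = (i < n1) ? 0 : 1;
      birth[i] = 0.0;
    }

    double t = 0.0;
    bool merged = (t_split <= 0.0);
    if (merged) for (int i = 0; i < n; ++i) deme[i] = 1;

    while (k > 1) {
      double rate1 = 0.0, rate2 = 0.0;
      if (!merged) {
        int k1 = 0;
        for (int i = 0; i < k; ++i) if (deme[i] == 1) ++k1;
        int k2 = k - k1;
        rate1 = (double)k1 * (k1 - 1);
        rate2 = (double)k2 * (k2 - 1);
        if (rate1 + rate2 <= 0.0) {
          // each deme down to <=1 lineage; jump to the merge
          t = t_split;
          merged = true;
          for (int i = 0; i < k; ++i) deme[i] = 1;
          continue;
        }
      } else {
        rate1 = (double)k * (k - 1);
      }

      double total = rate1 + rate2;
      double dt = R::exp_rand() / total;

      if (!merged && t + dt >= t_split) {
        // memoryless: restart the clock at the split
        t = t_split;
        merged = true;
        for (int i = 0; i < k; ++i) deme[i] = 1;
        continue;
      }
      t += dt;

      int target = 1;
      if (!merged && unif_rand() * total >= rate1) target = 2;

      // choose a random distinct pair within the target deme
      int kt = 0;
      for (int i = 0; i < k; ++i) if (merged || deme[i] == target) ++kt;
      int a = (int)(unif_rand() * kt); if (a >= kt) a = kt - 1;
      int b = (int)(unif_rand() * (kt - 1)); if (b >= kt - 1) b = kt - 2;
      if (b >= a) ++b;
      // map ranks back to indices
      int ia = -1, ib = -1, r = 0;
      for (int i = 0; i < k; ++i) {
        if (merged || deme[i] == target) {
          if (r == a) ia = i;
          if (r == b) ib = i;
          ++r;
        }
      }

      // finalize the two child branches
      blen[nb] = t - birth[ia]; b1[nb] = d1[ia]; b2[nb] = d2[ia]; ++nb;
      blen[nb] = t - birth[ib]; b1[nb] = d1[ib]; b2[nb] = d2[ib]; ++nb;

      // parent replaces ia; last active lineage moves into ib's slot
      d1[ia] += d1[ib];
      d2[ia] += d2[ib];
      birth[ia] = t;
      --k;
      if (ib != k) {
        deme[ib] = deme[k]; d1[ib] = d1[k]; d2[ib] = d2[k]; birth[ib] = birth[k];
      }
    }

    double L = 0.0;
    for (int i = 0; i < nb; ++i) L += blen[i];
    double u = unif_rand() * L, acc = 0.0;
    int hit = nb - 1;
    for (int i = 0; i < nb; ++i) {
      acc += blen[i];
      if (u <= acc) { hit = i; break; }
    }
    out(locus, 0) = b1[hit];
    out(locus, 1) = b2[hit];
  }

  return out;
}

// Total tree height (TMRCA) of the same process, for distributional checks.
// [[Rcpp::export]]
NumericVector sim_split_tmrca_cpp(int n1, int n2, double t_split, int n_loci) {
  NumericVector out(n_loci);
  const int n = n1 + n2;
  std::vector<int> deme(n);
  for (int locus = 0; locus < n_loci; ++locus) {
    int k = n;
    for (int i = 0; i < n; ++i) deme[i] = (i < n1) ? 1 : 2;
    double t = 0.0;
    bool merged = (t_split <= 0.0);
    while (k > 1) {
      double rate1, rate2 = 0.0;
      if (!merged) {
        int k1 = 0;
        for (int i = 0; i < k; ++i) if (deme[i] == 1) ++k1;
        int k2 = k - k1;
        rate1 = (double)k1 * (k1 - 1);
        rate2 = (double)k2 * (k2 - 1);
        if (rate1 + rate2 <= 0.0) { t = t_split; merged = true; continue; }
      } else {
        rate1 = (double)k * (k - 1);
      }
      double total = rate1 + rate2;
      double dt = R::exp_rand() / total;
      if (!merged && t + dt >= t_split) { t = t_split; merged = true; continue; }
      t += dt;
      int target = 1;
      if (!merged && unif_rand() * total >= rate1) target = 2;
      // remove one lineage from the target deme
      if (!merged) {
        for (int i = 0; i < k; ++i) {
          if (deme[i] == target) {
            deme[i] = deme[k - 1];
            break;
          }
        }
      }
      --k;
    }
    out[locus] = t;
  }
  return out;
}
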