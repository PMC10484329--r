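---
title: "Models and methods behind beescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`beescan` studies ancestry-mediated local adaptation in admixed honey-bee
populations. This vignette explains the models behind each stage, the
parameters that matter and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical and design choices that were
genuinely open. It states no empirical result beyond what the package's own
tests and acceptance script compute.

## The study design being emulated

Two admixed Colombian worker populations (15 lowland, 14 highland diploid
samples) are compared against three reference panels: 19 African (A group)
workers, 9 East European (C group) workers and 85 Iberian (M group) haploid
drones. Genome-wide A ancestry averages 0.847 in the lowland and 0.686 in
the highland population; a small minority of loci carry a further ancestry
shift attributed to selection. All downstream machinery — filters, windowed
statistics, peak calling, the coalescent null, ancestry correlations — is
exercised against synthetic data generated under exactly this design, with
ground truth recorded for parameter-recovery tests.

## The synthetic-data generator

**Lineage frequencies.** Each SNP draws an ancestral frequency
`p ~ U(0.05, 0.95)` and per-lineage frequencies from the Balding–Nichols
Beta distribution with drift parameter `F` per lineage, i.e.
`Beta(p(1-F)/F, (1-p)(1-F)/F)`; `F` equals the lineage's expected FST to the
ancestral pool. SNPs monomorphic in all three lineages are redrawn.

Defaults are `F_A = 0.02`, `F_C = 0.70`, `F_M = 0.65`. Two constraints fix
them. First, expected diversity scales as `(1-F)`, which orders the
reference panels' nucleotide diversity as A > M > C, as observed in the
empirical panels. Second, under Balding–Nichols the cross-lineage
heterozygosity equals the ancestral heterozygosity, so an A/M mixture with
A fraction `alpha` has expected heterozygosity
`H_anc (1 - alpha^2 F_A - (1-alpha)^2 F_M)`; the A lineage out-diversifies
the admixed populations only when `F_A < F_M (1-alpha)/(1+alpha) ~ 0.054`
at `alpha = 0.847`. A small `F_A` is also the biologically sensible choice:
African populations retain most ancestral diversity while the European
lineages are strongly bottlenecked.

**Admixed genotypes.** Each allele copy of an admixed individual draws its
lineage independently (A with the population's proportion, C with 0.001, M
otherwise) and then its allele from that lineage's frequency. Per-copy
independence means no linkage blocks; the per-SNP statistics in scope do not
require realistic tract lengths. Selection targets are an exception: each of
the `n_selected_loci` target loci (default 4, mutually separated by at least
three windows) depresses the highland A proportion by
`selection_ancestry_shift` (default 0.5) across a `selection_region_bp`
tract (default 30 kbp). A tract spanning three scan windows guarantees one
fully shifted window per target — a single shifted SNP among ~20 per window
could never dominate the window's ratio-of-sums — with partially shifted
flanks for the peak extension to absorb, mirroring the empirical peaks'
spans of tens to hundreds of kilobases.

**Marker informativeness matters.** A fully shifted window can still be
missed when its SNPs happen to have `p_A ~ p_M` (uninformative ancestry
markers). At the default density of ~20 SNPs per 10-kbp window this is rare;
at half that density roughly one target in ten is missed. This is a real
property of ancestry-based scans, not an artifact.

**VCF emission.** Haploid drones are written as diploid homozygotes. An
injected fraction of sites receives artifactual heterozygous drone calls —
2.5% of sites with one heterozygous drone and 0.5% with two, matching the
rates reported for the empirical joint-called data. GATK-style annotations
(`QD, FS, MQ, MQRankSum, ReadPosRankSum, SOR`, site `QUAL`, per-sample `DP`)
are drawn from safely passing ranges, with configurable fractions engineered
to fail each rule for filter testing. Genotypes are missing completely at
random at rate 0.02.

**Reference genome, genes, recombination map.** Bases are iid at a
background GC of 0.35 (honey-bee-like), depressed by 0.15 inside one truth
centromere interval per chromosome (positions 30–60% of the chromosome;
at least 50 windows, the detector's minimum span). Multi-exon genes (3–8
exons of 150–500 bp) are placed on both strands, with one gene anchored over
each selection target so peak annotation has true positives. The
recombination map tiles the genome at window resolution with a flat 25
cM/Mb, times 0.3 in centromeres and 0.39 in selected windows — the empirical
observation that divergence peaks sit in low-recombination sequence.

**Ancestry posteriors.** For each Colombian individual and SNP the true
diplotype state (CC, CM, CA, MM, MA, AA) follows from the two copies'
lineages; the emitted posterior is Dirichlet with concentration
`0.5 + 1/noise` on the true state and 0.5 elsewhere. At `noise = 0` the
posterior is the exact one-hot truth. The default `noise = 0.05` emulates
confident HMM posteriors on dense markers. One caveat is intrinsic:
symmetric Dirichlet noise regresses posterior means toward the uniform
prior, so the lowland-highland ancestry difference attenuates by roughly
5–10% at the default noise. Truth-recovery tests of the design contrast
therefore run at `noise = 0`, where the attenuation vanishes by
construction. Cline steepness is drawn with a configurable correlation
(default 0.1) to the standardized true per-SNP ancestry shift.

**What the generator does not emulate:** linkage disequilibrium and ancestry
tract-length distributions (except inside selection targets), mutation
spectra, sequencing reads and genotype-likelihood error structure, the
chromosome 7/9 inversions, and population substructure or relatedness.
Passing recovery tests therefore demonstrate the statistics' correctness
under idealized sampling, not robustness to LD or calling error.

## Variant filtering

The cascade runs hard filters → site filters → drone handling → minor
allele count, and is a no-op on its own output. Comparators are exactly the
printed ones, strict where printed strict: a site fails hard filtering iff
`QD < 2`, `FS > 60`, `MQ < 40`, `MQRankSum < -12.5`, `ReadPosRankSum < -8`
or `SOR > 3` (boundary values pass; missing annotations never fail a rule,
since callers omit rank-sum annotations at sites without heterozygotes).
Site filters retain bi-allelic SNPs with `QUAL > 100` (strict), mean
per-sample depth ≤ 20 (inclusive maximum; computed from FORMAT `DP` over all
samples, sites with no depth values skip the rule), and missingness < 30% in
every population (removal at 30% exactly). Heterozygous calls in haploid
drones are artifacts: one heterozygous drone masks that genotype, two or
more remove the site. The minor allele count filter keeps MAC ≥ 3, counting
one allele copy per drone. Diversity estimation deliberately uses the
MAC-free panel, since a count filter excludes the rare variants that π and
θ_W weight.

The per-sample inbreeding coefficient is the homozygosity-excess
method-of-moments estimator `F = (O_hom - E_hom)/(n - E_hom)` with per-site
`E_hom = 1 - 2p(1-p) n/(n-1)` from panel allele frequencies — the definition
used by the standard VCF toolkit's `--het`. Diploid-coded drones have `F`
near 1; a drone far below is flagged as unreliable. SNP thinning is greedy
left-to-right (keep a site iff ≥ 500 bp beyond the last kept site), which
guarantees the pairwise-distance bound and matches the cited tool.

## Diversity and divergence statistics

Per-site diversity is `2 p (1-p) n/(n-1)` over called allele copies, summed
in 50-kbp windows and divided by window length; the genome value is the
unweighted mean over windows with data. Haploid drones are first paired
randomly (seeded) into pseudodiploids, the odd drone dropped and logged.
Watterson's θ is `S / (a_n L)` with `a_n` the harmonic number over sampled
chromosomes.

Per-SNP FST uses the Weir–Cockerham (1984) two-population variance
components — the full a/b/c decomposition with observed heterozygosity for
diploid pairs, the allele-count mean-squares form (zero heterozygosity,
single copies per drone) when a population contains haploids. Negative
per-SNP estimates are retained unclamped so ratio-of-sums aggregates match
the reference tools. Windows tile each chromosome from position 1; the
window value is Σ numerators / Σ denominators. The genome-wide value is the
same ratio-of-sums across all SNPs — the multi-locus coancestry estimator of
Reynolds, Weir & Cockerham (1983), whose variance components coincide with
the two-population Weir–Cockerham decomposition (no installed package
provides an independent transcription, so the equivalence is exploited and
the calibration is validated by simulation: at split time `t` in 4N units
the estimator converges to `1 - exp(-2t)`).

Kinship is the KING-robust within-pair estimator
`phi = (N_het,het - 2 N_opposite-hom) / (N_het(i) + N_het(j))` over shared
called sites, with 0.044 — the published threshold for any degree of
relatedness — as the flag level.

## Pericentromere detection

GC content is computed in 10-kbp windows, excluding N bases from numerator
and denominator; all-N windows are undefined and score 0. Windows score +1
below the genome-mean GC, −1 above, 0 at equality. Per chromosome the
cumulative score runs left to right from zero. The detector seeds on the
50-window span with the maximum net score gain ("highest increase in the
cumulative score"), ties leftmost — the only reading consistent with a
cumulative track. Chromosomes whose best span has non-positive gain yield no
region. The seed extends in 10-window blocks while a block's net score is
≥ +5 (partial blocks at chromosome edges are not absorbed), then by single
windows while the adjacent score is +1. The block-extension rule is applied
as stated, without re-checking any whole-region criterion; the randomized
equivalence suite pins the implementation to an exhaustive step-by-step
oracle on chromosomes up to 500 windows.

## FST peaks, genes, enrichment

Thresholds are the empirical 0.998 / 0.99 / 0.98 quantiles of the defined
window values, with the linear-interpolation (type 7) definition — a
convention had to be fixed for reproducibility. Contiguous runs of windows
≥ Q0.998 form seeds (adjacent seed windows merge; gaps are never jumped).
Extension alternates sides starting left — the order is unspecified in the
source procedure, so it is fixed deterministically and the brute-force
oracle mirrors it — accepting a window iff its value is ≥ Q0.98 and the
extended peak's SNP-count-weighted mean FST stays ≥ Q0.99, evaluated after
every single-window acceptance (the stricter of the two possible readings).
The peak's weighted mean is `sum(n_i v_i)/sum(n_i)` over member windows with
their SNP counts, i.e. a weighted mean of window values rather than a
re-pooled ratio-of-sums; the two differ only when window denominators vary
wildly within a peak.

A gene is annotated to a peak iff at least 30% of its exons overlap the
peak by at least 50% of the exon's length. Gene-wise FST is the
ratio-of-sums over SNPs inside the transcript bounds (introns included —
the simplest reading of gene coordinates). Term enrichment uses the
upper-tail hypergeometric probability `P(X >= k)` with Benjamini–Hochberg
correction across terms at FDR 0.05. Peak recombination is the
length-weighted mean map rate inside the peak divided by the length-weighted
chromosome mean; peaks overlapping detected pericentromeres are flagged, not
removed.

## The coalescent null

The null model is an ancestral population splitting into two demes of
unchanged, constant, equal size with no gene flow. Time is measured in 4N
generations with within-deme coalescence rate `k(k-1)` for `k` lineages
(the convention of the classic command-line simulator this reproduces);
after the split the remaining lineages coalesce panmictically. Exactly one
mutation is placed uniformly at random along the total non-root branch
length, so every exported SNP segregates; per-SNP FST is the haploid
Weir–Cockerham form on the per-deme derived counts. With one fixed
segregating site the locus mutation rate (906 bp × 0.00467/bp = 4.23) does
not affect the exported SNP's distribution; it is retained for interface
parity with the source command. The panel simulator is compiled (Rcpp), with
a pure-R genealogy path kept as an internal cross-check; the compiled path
is additionally validated distributionally against an independent coalescent
simulator (msprime) at the study parameters.

Parameterization follows the published procedure exactly: genome FST 0.0584
converts to `T = -ln(1 - FST)/2 = 0.0301` and the simulator input is
`T/2 = 0.0150`. Two subtleties deserve record. First, simulation shows the
4N-unit split time that reproduces a target FST is `T` itself (the
ratio-of-sums estimator converges to `1 - exp(-2t)`), so the halved input
corresponds to a ratio-of-sums FST of ~0.029, not 0.058. Second, the
dataset-level "average FST" conventions differ: the plain mean of per-SNP
estimates, the ratio-of-sums, and the mean over SNPs with positive estimates
(the per-site outlier-scan convention, which discards the non-positive
estimates that dominate low-information SNPs) give ~0.019, ~0.029 and ~0.052
respectively at the printed parameters. The summary object reports all
three; the acceptance script reports the positives-only mean, the convention
consistent with the published summary of this simulation. The enrichment
test counts SNPs above the threshold (default 0.255, the empirical
0.998 quantile at matched resolution) in the empirical and simulated
distributions and reports the ratio after scaling to equal totals.

One distributional note: with exactly one mutation per genealogy the site
frequency spectrum weights each tree by `L_i/L` rather than `L_i`, so it is
close to, but not exactly, the neutral `1/i` law; the test suite asserts
total-variation closeness rather than an exact-law fit.

## Ancestry statistics

Diplotype posteriors reduce as `p(A) = p(AA) + (p(MA) + p(CA))/2`, with the
analogous reductions for C and M so the three sum to 1 (enforced to 1e-6 on
input rows). Population tracks are per-SNP means over individuals;
Δ = lowland − highland. The FST-ancestry association is Spearman's
rank correlation between window FST and the window-averaged Δ
(window-averaging chosen because the FST scan is windowed; the source
analysis does not state which it used). The cline comparison is Pearson's
correlation over the SNP intersection.

Two overlapping dependent correlations (sharing the focal population) are
compared with Dunn & Clark's z using the backtransformed-average Fisher Z —
the Hittner, May & Silver (2003) variant named by the source's citation.
`n` is the number of SNPs in the intersection; SNP autocorrelation is
ignored exactly as in the source analysis, which makes the nominal p-values
anti-conservative for clustered signals — a documented caveat, and the
reason the type-I-error test allows 1.5× the nominal rate. External
populations are classed by genome-wide A ancestry (below the highland
level, or between highland and lowland levels; others excluded and logged)
and the class × "significantly higher correlation with highland" table is
tested with a two-sided Fisher's exact test implemented by hypergeometric
enumeration (validated against `stats::fisher.test` over all small-margin
tables). The significance cutoff for "significantly higher" defaults to
0.001; the source prints both 0.001 and 0.0001 in different places, so the
cutoff is a parameter rather than a constant.

The synthetic external populations used in sign-recovery tests share the
panel's selection targets with a shift scaled linearly by how highland-like
their genome-wide ancestry is — the study's premise that similar climates
select on the same loci, reduced to its minimal generative form.

## Problem sizes and determinism

Default generator panels are 40,000 SNPs on five 4-Mb chromosomes (2,000
scan windows, ~20 SNPs per window, 4 selection targets — the same ~0.2%
outlier-window fraction as 14 peaks among ~22,000 empirical windows).
Recovery experiments in the test suite use 18,000 SNPs on three 3-Mb
chromosomes across 20 seeds; the coalescent acceptance run uses the full
248,598 loci, which the compiled simulator completes in seconds. Every
stochastic step takes an explicit seed, stage seeds derive from one master
seed by fixed offsets, and identical configuration plus seed reproduces
byte-identical outputs.

## Known limitations

Per-SNP ancestry assignment without linkage blocks understates the spatial
autocorrelation of real local-ancestry tracks, so correlation p-values on
synthetic data are better calibrated than they would be on real genomes.
The filter cascade trusts the emitted annotations rather than re-deriving
them from reads. The Reynolds genome-wide estimator is implemented through
the Weir–Cockerham components (the two coincide for two populations) rather
than the 1983 paper's own algebra. The coalescent null inherits the
published model's simplifications: constant equal deme sizes, no migration,
no recombination-rate variation among loci.
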