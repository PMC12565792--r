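---
title: "Detecting polymorphic chromosome inversions from SNP genotype matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polymorphic chromosome inversions from SNP genotype matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invscan)
```

## The problem

A polymorphic chromosome inversion suppresses recombination between the
standard and inverted arrangements across a multi-megabase interval. In a
population sample, the suppressed interval behaves like a single biallelic
"super-locus": every sample carries 0, 1 or 2 inverted haplotypes (the
karyotypes AA, AB, BB), SNPs inside the interval are in unusually strong
mutual linkage disequilibrium (LD), and allele frequencies at many inside
sites diverge between arrangements. `invscan` exploits exactly this
footprint to detect inversions from nothing but a biallelic-SNP diploid
genotype matrix — the kind of data produced by imputing low-coverage
whole-genome sequencing — without haplotype phasing, breakpoint-spanning
reads or cytogenetics.

The detection signal is built from a per-chromosome principal component
analysis of the standardized dosage matrix. Because the karyotype is a
single axis of inter-sample variation supported by thousands of inside
SNPs, an inversion shows up as (i) a principal component whose sample
scores separate into three clusters, and (ii) a localized block of SNPs
with large loadings on that component. The package measures (ii) with a
sliding-window variance of the component's SNP weights: inside the
inversion, weights are large and heterogeneous, so the window variance is
elevated over a contiguous block; outside, weights hover near zero.

## Pipeline

`detect_inversions()` is the single fitting function; it chains the
following stages and returns a classed object with `print`, `summary` and
`plot` methods.

1. **Marker filtering** (`filter_variants`): drop SNPs with minor allele
   frequency below 0.1 or missing in at least half the samples, then drop
   samples missing at least half the surviving SNPs.
2. **LD pruning** (`ld_prune`): greedy windowed indep-pairwise pruning,
   14 kbp windows stepped by 9 kbp, removing one member of any pair with
   dosage r² > 0.05 (the lower-MAF member; tie broken downstream). Pruning
   leaves an approximately exchangeable marker set so that PCA is not
   dominated by a few tightly linked clusters; enough inversion-informative
   sites survive (roughly one per window) because the inversion's LD block
   spans hundreds of windows.
3. **Scan** (`chromosome_pca`, `windowed_weight_variance`,
   `detect_candidate_regions`): PCA per chromosome (5 components by
   default), then for each component the unbiased variance of SNP weights
   in 10 kbp windows stepped by 7.5 kbp, anchored at the chromosome's first
   SNP; windows with fewer than 3 SNPs carry no value.
4. **Karyotyping** (`karyotype_component`): the top 1% of SNPs by absolute
   weight feed an identity-by-state similarity matrix; classical MDS of
   `D = 1 − IBS` at `k = 1` gives a one-dimensional embedding that fuzzy
   c-means splits into three clusters; samples are called AA/AB/BB by
   maximal membership, orienting the larger homozygote cluster as AA so the
   minor-arrangement frequency is at most 0.5.
5. **Coordinates** (`association_scan`, `estimate_coordinates`): ordinary
   least squares of the 0/1/2 karyotype phenotype on each SNP's dosage,
   Bonferroni correction over the chromosome's polymorphic SNPs, and the
   densest gap-linked cluster of significant SNPs (gap 1 Mb) defines the
   coordinate estimate.
6. **LD corroboration** (`collect_pairs`, `windowed_median_r2`,
   `weight_ld_correlation`): all pair r² within 12 kbp, the median per
   window of 0.5% of the chromosome length (stepped by half a window), and
   the Spearman correlation between that profile and the mean absolute SNP
   weight per window.
7. **Inversion comparisons** (`pairwise_inversion_tests`): Spearman tests
   between the karyotype vectors of all retained inversion pairs with
   Benjamini–Hochberg control, plus a chi-square test on the 3×3 genotype
   table.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `maf_min` | 0.1 | minimum minor allele frequency retained |
| `prune_window_bp` / `prune_step_bp` / `prune_r2` | 14000 / 9000 / 0.05 | LD-pruning window, step (bp) and r² ceiling |
| `window_bp` / `step_bp` / `min_snps` | 10000 / 7500 / 3 | weight-variance window, step (bp), minimum SNPs per window |
| `n_components` | 5 | PCA components scanned per chromosome |
| `flag_quantile` / `flag_fold` | 0.95 / 5 | window-flagging thresholds (see below) |
| `min_run` / `max_gap` | 10 / 2 | flagged-window chaining rules |
| `top_fraction` | 0.01 | fraction of SNPs used for karyotyping |
| `alpha` | 0.05 | significance level on Bonferroni-adjusted p |
| `merge_gap_bp` | 1e6 | gap linking significant SNPs into one estimate |
| `ld_max_dist` | 12000 | maximum LD pair distance (bp) |
| `ld_window_frac` | 0.005 | LD window as a fraction of chromosome length |

The variance windows need a minimum SNP count (3) because the unbiased
variance of one or two weights is undefined or wildly unstable; windows
below the count carry no value and are treated as unflagged.

### Flagging and chaining

"High-shifted" is quantified with two complementary thresholds: a window is
flagged when its variance exceeds the 95% quantile of all defined windows
**or** five times their median. The quantile clause captures the profile's
upper tail when the elevated block is small; the fold-over-median clause is
what lets a *broad* block be flagged contiguously — when an inversion spans
a large fraction of the chromosome (40% in the validation design below),
the 95% quantile itself lies inside the block and exceeding it would flag
only a scattered tail, so requiring both thresholds simultaneously would
make broad inversions undetectable by construction. On a flat profile
neither clause fires: no value exceeds five times the median, and the
quantile excess alone cannot assemble the required run of 10 flagged
windows with at most 2 bridged gaps, which is what keeps the null clean.
All four knobs are exposed.

### Karyotype retention

A candidate component is retained only when the three clusters are
"well-defined": each cluster has at least 3 samples, the mean maximal
membership is at least 0.8, and the middle center sits at a relative
position within [0.3, 0.7] between the homozygote centers. Under
Hardy–Weinberg karyotype sampling the heterozygote cluster sits near the
midpoint of the 1-D embedding, so the spacing rule is a direct quality
check on the three-cluster geometry; failing components are reported with
the violated rule, never silently dropped.

## Numerical choices

* **Standardization**: dosages are scaled as `(d − 2p)/sqrt(2p(1−p))` (the
  usual genotype-PCA convention), missing entries set to 0 after centering
  (mean imputation), monomorphic columns dropped. Post-imputation data has
  little missingness, so mean imputation is benign.
* **PCA determinism**: eigendecomposition of the smaller Gram matrix;
  each component's sign is fixed so its largest-|weight| SNP has a
  positive weight. Sample score variance equals the eigenvalue exactly.
* **MDS**: classical scaling of `D = 1 − IBS` via `stats::cmdscale`
  (negative eigenvalues dropped), axis signs fixed like PCA components.
  The alternative reading of a "Euclidean" IBS distance — Euclidean
  distance between IBS-matrix rows — produces the same three-cluster
  geometry up to scale on simulated inversions; the simpler `1 − IBS`
  form is used.
* **Fuzzy c-means**: deterministic range-based initialization — centers
  start at the 1% quantile, the 99% quantile and their midpoint —
  fuzzifier `m = 2`, convergence when centers move less than 1e-6; a
  point coinciding with a center gets membership 1 there. Range-based
  starts matter: under Hardy–Weinberg at intermediate inversion frequency
  the minor homozygote cluster holds under 10% of samples, so
  probability-quantile starts (e.g. 1/6, 3/6, 5/6) place two centers
  inside the big clusters and FCM can converge to a local optimum that
  splits one of them; because the three karyotype clusters are near
  equally spaced on the embedding, low/mid/high starts land one center
  near each cluster whatever the class proportions. The only stochastic
  element in the whole pipeline is a tiny seed-controlled jitter applied
  if initial centers collide, so runs are reproducible given the seed.
* **Association**: slope t-tests via closed-form simple regression on
  pairwise-complete samples; monomorphic SNPs get `p = 1` so they can
  never reach significance.
* **Ties**: top-weight selection breaks |weight| ties toward the lower
  position; Spearman tests use average ranks with the asymptotic p-value.

## The simulator and what it does (not) emulate

`simulate_inversion_dataset()` generates the statistical footprint the
detector exploits, at the genotype level. Karyotypes are Binomial(2, q)
per sample (Hardy–Weinberg). Outside inversions, sites are independent
Binomial(2, p) draws with p uniform on the background MAF range — no
background LD. Inside an inversion, a site is "divergent" with probability
`d` (arrangement frequencies ε and 1 − ε, ε = 0.02), otherwise the two
arrangement frequencies are independent Balding–Nichols draws around the
ancestral frequency with drift `Fst = 0.2`, which creates the
intermediate-LD background that makes PCA loadings — not only fixed
differences — informative. Post-imputation genotyping error is emulated by
replacing each dosage with a uniform {0,1,2} draw with probability `e`
(defaults to 0.1, i.e. roughly 90% genotype concordance, the scale
reported for imputed ~2× data) and by a small residual missing rate.

The simulator deliberately does **not** model read-level noise, reference
bias, genuine recombination maps, background LD outside the inversion,
population structure or relatedness. Passing the recovery tests therefore
shows that the statistical machinery extracts the inversion footprint it
was designed for; it does not certify performance against confounders real
data may add (admixture gradients, centromeric LD, assembly errors), which
is why the candidate-region thresholds and retention rules are exposed
rather than hard-coded.

## Validation design and problem sizes

The package's own validation (exercised by the test suite and by
`scripts/acceptance.R`) simulates 200 samples on a 20 Mb chromosome at
2.1 SNPs/kb with one inversion spanning 6–14 Mb at frequency q = 0.3,
divergence 0.3, 10% genotype error, over 20 seeds, with 20 matched null
runs. These sizes keep a full 40-run validation within a few minutes on a
single core while preserving the regime that matters: thousands of SNPs
inside the inversion, intermediate inversion frequency, and genotype error
at the imputed-low-coverage scale. Module-level property tests use a 2 Mb
/ 120-sample miniature of the same design over 50 seeds.

On this design the pipeline typically recovers the karyotypes of all
samples (median concordance 1.0), estimates coordinates with Jaccard
overlap above 0.99 against the true interval, places the heterozygote
cluster within a few percent of the embedding midpoint, and yields a
positive, significant Spearman correlation between the windowed median r²
and the mean absolute SNP weights — the same qualitative corroboration
seen on real imputed low-coverage data, where such correlations fall
around 0.4–0.9.

## Known limitations

* Breakpoint resolution is bounded by the association signal's edges;
  offsets of tens to hundreds of kb from the true breakpoints are expected
  at low coverage, and the method makes no attempt at base-pair precision.
* Nested or overlapping inversions are out of scope for the simulator and
  untested for the detector (a large inversion can spread across several
  components in practice).
* The scan assumes the arrangement axis lands in the first few principal
  components; strong population structure on the same chromosome can
  displace it.
* The LD profile needs chromosome lengths (from VCF contig headers or a
  TSV); without them that corroboration stage is skipped.
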