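---
title: "Temporal genome scans in predominantly selfing populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal genome scans in predominantly selfing populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`temposcan` targets the "resurrection" design: the same population is
sampled twice, a few decades apart, and loci whose allele frequencies moved
more than drift can explain are flagged as selection candidates. This
vignette walks through the statistical machinery and the numerical choices
behind it, then runs a compact end-to-end example.

## Study setting

The motivating setting is a panel of rice landraces from a region that has
experienced rapid drying and warming: roughly 31 generations separate the
two collections, the crop is ~95% selfing, and the samples are genotyped at
genome-wide SNPs. Three properties of this setting drive the design:

1. **Small effective size.** Decades of drift in a small population can move
   frequencies dramatically; outlier tests must condition on an estimate of
   `Ne` obtained from the data themselves.
2. **Extreme inbreeding.** Under selfing rate `s`, the equilibrium
   inbreeding coefficient is `FIS = s / (2 - s)` (0.90 selfing gives
   FIS = 0.818); genotypes are mostly homozygous, so any null that resamples
   genotypes must respect the observed FIS rather than Hardy–Weinberg.
3. **Genetic draft.** With near-complete selfing, recombination is rare in
   effect and fitness is nearly perfectly heritable, so selection at a few
   loci perturbs the whole genome (see the closing section).

## Filtering and core statistics

`filter_loci()` applies strict thresholds appropriate for GBS data from
highly homozygous material: minor allele frequency strictly above 1%,
missingness strictly below 20%, and heterozygote fraction strictly below 5%
(residual heterozygosity in a landrace panel mostly signals paralog
collapse). For a `temporal_pair` the statistics are computed on the pooled
samples so both retain identical locus lists.

`locus_summaries()` reports per-locus identity probabilities: the unbiased
within-sample gene-identity `f0` (counting ordered gene pairs without
replacement), the between-sample identity `f1 = p1 p2 + q1 q2`, the derived
heterozygosities, and two per-locus FST estimates — the identity-based
`(f0 - f1) / (1 - f1)` and the Weir–Cockerham variance-components estimate.
`fst_weir_cockerham()` gives the multilocus ratio-of-sums global estimate,
and `multilocus_fis()` the ratio-of-sums FIS; both use the r = 2
Weir–Cockerham components computed from genotype class counts, which remain
valid under inbreeding. The test suite checks them against an independent
allele-level ANOVA implementation.

## The drift scan

`drift_scan()` builds a locus-specific null for the temporal FST:

1. `Ne_hat = tau * (1 - FST_global) / (4 * FST_global)` (`estimate_ne()`).
2. For each locus, a starting frequency is drawn from a Dirichlet
   (equivalently Beta) posterior with a +1 smoothing count on the observed
   first-sample allele counts, then propagated through `tau` generations of
   binomial drift with `2 * Ne_hat` gene copies per generation.
3. Genotypes for **both** samples are resampled at their observed sizes from
   the simulated start and end frequencies with the observed multilocus FIS
   (full-sib structure of homozygotes/heterozygotes), and the Weir–Cockerham
   FST is recomputed.
4. The one-sided p-value is the tail count
   `p = (1 + #{FST_sim >= FST_obs}) / (1 + n_sim)`; simulated draws that are
   non-estimable do not count toward the tail, and loci monomorphic in the
   pooled pair are skipped. The Weir–Cockerham estimator is allowed to go
   negative in both the observed and simulated values, so the null p-values
   stay uniform instead of piling mass at 1.
5. `qvalues()` converts p-values to Benjamini–Hochberg (default) or Storey
   q-values; `q < 0.05` calls an outlier.

## The FDist-style scan

`fdist_scan()` compares each observed `(heterozygosity, FST)` pair against a
null cloud simulated under a hierarchical island model: `k` groups of `d`
demes, coalescent simulation with migration within and between groups, and a
single mutation placed on a branch chosen proportionally to its length
(compiled in `src/` via Rcpp). Two samples of haploid size `2 n` are read
from two demes.

- `calibrate_migration()` tunes the between-deme migration rate by log-scale
  bisection (seeded from the closed-form island approximation
  `FST = 1 / (1 + M (d/(d-1))^2)`) until the simulated global FST matches
  the observed one within 10%. The target is floored at 0.005: below that,
  sampling noise in a pilot cloud swamps the signal and the null is
  effectively panmictic anyway.
- `kernel_pvalue()` computes, for each observed locus, the
  Gaussian-kernel-weighted probability that a cloud point at the observed
  heterozygosity has FST at least as large (bandwidth `bw.nrd0` on the
  cloud's heterozygosities; floored at `1 / (n_cloud + 1)`).
- `quantile_envelope()` bins the cloud into 25 heterozygosity bins (at least
  50 points per bin) and records the empirical upper 5% and 1% FST
  quantiles; `classify_envelope()` labels observed loci `ns`, `sig5`, or
  `sig1`. A fresh cloud simulated under the same parameters falls beyond the
  envelopes at the nominal rates, which the acceptance tests verify.

## From SNPs to regions

`cluster_snps()` chains significant SNPs into clusters when consecutive SNPs
on a chromosome are separated by less than 250 kb **and** have `r^2 > 0.2`
(an or-rule is available). `merge_loci_groups()` unions clusters found in
different genetic groups transitively. `classify_and_extend()` labels each
cluster `M2` if at least one member SNP is significant under *both* scans
and `M1` otherwise, discards single-SNP clusters supported by a single
method, and extends each region by 250 kb on both sides, clipped to the
IRGSP-1.0 chromosome lengths. `overlap_annotations()`, `fold_enrichment()`
(hypergeometric) and `density_fold()` quantify the annotation content of the
resulting regions.

## Climate and phenology

`season_aggregate()` reduces monthly station series to wet-season values
(sum for rainfall, mean for temperature), `lamb_index()` standardizes them
against a 1961–1990 reference period (a perfectly flat series yields
all-zero anomalies), and `period_contrast()` gives between-period
differences. `dthd_contrast()` tests the days-to-heading advance between
collections within a genetic group with a Welch t-test plus normality
flags.

## A compact run

```{r example, message = FALSE}
library(temposcan)
pair <- simulate_temporal_population(
  n_loci = 300, ne = 200, selfing_rate = 0.95, tau = 31,
  n0 = 60, n_tau = 60, selected = c(80L, 220L), sel_coef = 0.8, seed = 11)
flt <- filter_loci(pair)
round(multilocus_fis(flt$pair), 3)

drift <- drift_scan(flt$pair, n_sim = 500, seed = 1)
fdist <- fdist_scan(flt$pair, k_groups = 4, d_demes = 6,
                    n_sim = 1000, n_pilot = 500, seed = 2)
table(drift = drift$table$class, fdist = fdist$table$class, useNA = "ifany")
```

The full pipeline, including ILUS construction and file outputs, is
`run_full_scan()`; the `analysis/` scripts in the package source run it at
study scale.

## Why the drift scan loses power under massive selection

The forward simulator (`simulate_temporal_population()`) makes fitness
multiplicative across selected loci, with selfing probability 0.95 and
equilibrium-inbreeding starting genotypes. When many loci sweep
simultaneously in such a population, offspring inherit their single parent's
entire genotype almost unchanged, so the selected lineages' *backgrounds*
sweep too. Genome-wide temporal FST then reflects draft, not drift:
`Ne_hat` collapses (often an order of magnitude below the census-derived
value), the simulated drift null becomes extremely wide, and per-locus
q-values rarely clear 0.05 — even at loci where selection drove an allele to
fixation. This is a property of the biology, not an estimator defect:
switching the same simulation to full outcrossing removes the inflation
entirely, and the neutral-only calibrations recover `Ne` and the nominal
false-positive rates. In practice this is why the two scans are paired: the
FDist null conditions on the realized genome-wide differentiation, so loci
that stand out *relative to the drafted background* remain detectable, and
regions confirmed by both methods (M2) are reported as the primary
candidates.
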