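---
title: "Methods: models, calibrations and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibrations and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations. It states no empirical result that the test suite does not
itself compute.

## The scientific setting

The pipeline targets a recurring situation in plant population genomics: a
highly selfing annual distributed across contrasting climates, structured
into a handful of deeply diverged clades nested in lineages, in which one
wants to connect (i) vernalization-response phenotypes measured in
replicated cold treatments, (ii) environmental covariates correlated with
that structure, and (iii) genome-wide signals of polygenic selection on
candidate flowering-time genes. Every analytical stage must contend with the
same confounder: in a selfer with no migration between clades, drift alone
produces strong allele-frequency differentiation and long-range linkage
disequilibrium, so each selection signal needs an explicit neutral
calibration.

## Flowering traits from replicated vernalization experiments

The experiment design is five cold durations (2, 4, 6, 8, 10 weeks at
4 degrees C) with three replicates per accession and duration, scoring days
from the return to warm conditions until spike emergence, every two days.
Four traits are extracted per accession:

* **MTD** (minimum threshold duration, weeks): the smallest tested duration
  whose cell is *permissive*, i.e. where a majority of replicates flowered.
  If that is the smallest tested duration the value is left-censored.
* **days to flower after MTD**: mean days after return at the MTD.
* **vernalization saturation** (weeks): the smallest permissive duration
  beyond which no tested longer duration shortens flowering by more than a
  tolerance. The tolerance defaults to 2 days — the scoring grid of the
  assay — because a "no further reduction" rule is not meaningful below
  measurement resolution. Landing on the largest tested duration while the
  curve is still improving sets a right-censoring flag.
* **days to flower after saturation**: counted from entry into the cold
  chamber, i.e. `7 * saturation_weeks` plus the mean days after return at
  saturation.

Accessions in which no cell is permissive are flagged `never_flowered` and
excluded from trait analyses. Two rules are package decisions where the
verbal protocol is silent: permissiveness requires a strict majority of
replicates (2 of 3), and non-monotone response curves are re-scanned
left-to-right with the same tolerance rule.

## Redundancy analysis and double-stopping forward selection

Trait-environment and trait-SNP associations use redundancy analysis: least
squares of a centered response on a centered design, with `R2` the fraction
of response variance captured by the fitted values and the Ezekiel
adjustment `R2adj = 1 - (1 - R2)(n - 1)/(n - m - 1)` as the selection
currency (`m` counts fitted coding columns, so a categorical
cluster-of-origin factor is admitted or rejected as a block). Forward
selection mirrors the `ordiR2step` semantics: at each step the candidate
maximizing cumulative `R2adj` is tested by permutation (free permutation of
the response from the empty model, residual permutation under the reduced
model afterwards; add-one p-value `(1 + #exceedances)/(1 + n_perm)`), and is
admitted only if it improves the cumulative `R2adj`, its p-value is at most
`Pin` (default 0.01, 1000 permutations), and the cumulative `R2adj` does not
exceed the adjusted R2 of the full model containing all candidates
(`R2scope`). The improvement condition is part of the reference semantics
(verified directly against `vegan`) even though it is easy to overlook.

One behavior deserves emphasis because the tests exercise it: when exactly
one strong predictor sits among pure-noise candidates, the full-model
`R2adj` is *diluted* by the noise terms and can fall below the single
predictor's `R2adj`, in which case the scope rule (faithfully) refuses every
step. Power analyses of the admission test itself therefore run with
`R2scope = FALSE`; the scope cap is asserted separately, as an exact
inequality on traces produced with it enabled. The reported AIC-like score
(`n log(RSS/n) + 2(m + 1)`) is informational parity with the trace table
format and never drives selection.

## Weir-Cockerham F_ST and the forward-simulation null

Per-site differentiation between two populations uses the Weir-Cockerham
(1984) variance components `a`, `b`, `c` with per-site, per-population
sample sizes from the non-missing calls; `theta = a/(a + b + c)`, undefined
for sites monomorphic across the pooled sample. Two summaries are exposed
deliberately: the per-site values (for outlier quantiles) and the
multi-locus **ratio of sums** `sum(a)/sum(a + b + c)`, which is the
combination rule the original estimator prescribes. The distinction matters:
the mean of per-site ratios is Jensen-biased low by roughly 10% in drift
regimes and cannot match analytic expectations; the ratio of sums is
unbiased, and the drift-calibration test (two populations of N = 200
diploids, 50 generations after an exact-copy split, expectation
`1 - (1 - 1/(2N))^t`) is asserted on it with a bootstrap-over-loci standard
error.

The neutral null is a forward Wright-Fisher simulation of the configured
split/bottleneck demography — discrete generations, per-offspring selfing
probability, crossover recombination, infinite-sites-style mutation, no
migration — run (by default) 100 times, pooling per-SNP `theta` into an
empirical distribution whose quantiles (third quartile, top-5% cut) feed
outlier calling. Children at a split copy individuals from the parent
without replacement when sizes permit, so a same-size split is an exact copy
and divergence starts at the split itself.

## X^T^X with pseudo-observed-dataset calibration

The covariance-aware differentiation statistic standardizes per-site
population frequency deviations by the estimated ancestral frequency
(`alpha_j = (p_j - pi)/sqrt(pi(1 - pi))`, `pi` the allele-count-weighted
mean) and whitens them with the inverse of the scaled across-population
covariance Omega. Three numerical decisions define this implementation:

1. **Deviation subspace.** Because `pi` is the count-weighted mean,
   `alpha` lies exactly in the hyperplane orthogonal to the count vector;
   Omega is estimated and inverted in that (J-1)-dimensional subspace. A
   full-space inverse is structurally singular and, once clamped positive
   definite, catastrophically miscalibrated. Consequently X^T^X is
   approximately chi-squared with J - 1 (not J) degrees of freedom — one
   degree is spent estimating `pi`.
2. **Sampling correction.** The expected binomial sampling variance of each
   population frequency estimate, rescaled to `alpha` units, is subtracted
   from the diagonal (toggleable); without it small samples inflate
   apparent drift.
3. **Moment matching through truncation.** The POD generator draws
   `pi ~ Beta(a, b)`, frequencies from a multivariate normal truncated to
   [0, 1], then binomial counts. Under truncation, naive moment estimates
   are not self-consistent: simulating from the raw estimate and
   re-estimating yields systematically smaller covariances, which made the
   closed-loop calibration fail by a factor of two to three in prototyping.
   The generator parameters (covariance and Beta moments) are therefore
   iterated until data simulated from the fitted model reproduce the
   observed deviation moments. This is a consistency fix in the estimator,
   not a tuned constant.

Significance uses the 0.99 quantile of X^T^X computed on a 100,000-locus
POD. Any threshold computed for a particular real panel is a function of
that panel's Omega and cannot be reproduced without its data; what is
testable — and tested — is the calibration property: the threshold
recovers an approximately 1% exceedance on fresh data from the generating
model.

## Linkage disequilibrium and the inter-chromosomal null

LD is the squared Pearson correlation of dosage vectors over
pairwise-complete accessions (the genotype-correlation convention). Decay
curves bin intra-chromosomal pairs by distance (half-open bins) after 20-kb
thinning, with a bootstrap percentile CI of the per-bin mean (1000 draws) —
a "95% CI" of a decay curve admits several constructions and
this choice is recorded here. The long-range null re-samples sets of `k`
loci from a random genic pool (default 50,000 resamples), computing the
mean cross-chromosome r^2 per set; the 2.5/97.5 percentiles of those means
form the CI against which a focal candidate-gene set is compared, with
per-chromosome configuration matching of the focal set as the default.
Near-1 r^2 values are snapped to exactly 1 (at 1e-12) so that perfect LD —
the criterion of the plink-style pruning step — is exactly representable.

A property of selfing worth flagging: with selfing at 0.99 even *unlinked*
loci show r^2 far above the 1/n outcrosser baseline (identity
disequilibrium). The test suite asserts both regimes; the 1/n baseline
check uses an outcrossing configuration.

## Mixed-model association and peak calling

Kinship is the centered cross-product `W_c W_c' / p` (missing dosages
mean-imputed for this computation only). The per-SNP model
`y = mu + x beta + u + e`, `u ~ N(0, sg^2 K)`, is fit by eigendecomposing K
once, rotating, and profiling `lambda = sg^2/se^2` per SNP by bounded
scalar REML optimization on the log scale in [1e-5, 1e5]; the Wald
`beta/se` is referred to a t distribution on n - 2 degrees of freedom, so
with `K = I` the scan reproduces ordinary least squares exactly. SNPs with
missing calls fall back to a complete-case fit with the corresponding
kinship submatrix. Marker significance is Benjamini-Hochberg at 0.05 (the
conventional level; configurable and recorded in the output), and regions are called where 8-kb windows
stepped by 4 kb contain at least four significant markers, merging
overlapping qualifying windows — unmerged windows would double-report.

## The synthetic world: what it does and does not establish

The generator states one fixed world per experiment; none of its parameters
were revisited after observing test outcomes (the two method-level fixes —
the deviation subspace and the truncation moment matching — are documented
above and in the decisions ledger as estimator corrections).

* **Demography defaults.** Five clades in three lineages, bottleneck-able,
  selfing rate 0.99 (the target organisms are highly selfing annuals whose
  exact rates are rarely measured), no migration. Real panels' demographic
  parameters (split times, sizes) are never shipped with this package, so
  the defaults are declared placeholders for a plausible history, not a
  claimed match to any particular one.
* **Standing variation.** Root populations can start monomorphic (mutation
  plus long burn-in), from independent per-site frequencies (uniform or a
  1/x spectrum; no initial LD — used for drift calibrations where loci must
  be independent), or from a haplotype-copying pool with blocky seed
  patterns, which produces haplotype-block local LD at initialization and
  stands in for a deep coalescent history that would otherwise require
  thousands of burn-in generations. The GWAS power world uses the pool
  initializer with approximately 5,000 post-filter SNPs at 800-bp spacing,
  so that an 8-kb window holds about ten markers.
* **Response curves.** Between MTD and saturation, days to flower declines
  linearly in duration at 7 days per missing week (the protocol specifies
  only the two thresholds, not the curve shape); replicate noise is
  Gaussian (sd 2 days by default, matching the scoring grid), rounded to
  the 2-day grid; censoring is a deterministic threshold with a 150-day
  horizon after return.
* **Environment.** Multivariate normal around clade means — correlated
  with structure exactly insofar as clade means differ. No spatial
  autocorrelation, raster extraction, or non-Gaussian climate variables.

A green suite therefore establishes internal correctness and calibration of
the statistics under these stated worlds; it does not establish that the
generator reproduces the spectrum, LD, or trait architecture of any real
panel, and no panel-specific empirical numbers (model R^2 values, LD
between named genes, outlier thresholds, heterozygosity percentages) are
asserted anywhere.

## Known limitations

* The forward simulator is unsuited to very long burn-ins at genome scale
  in pure R; the pool initializer is the intended substitute.
* `X^T^X` here is a moment-based statistic with POD calibration, not the
  Bayesian MCMC of the original tool; the preserved contract is
  covariance-aware differentiation with a POD 0.99 threshold.
* RDA handles missing data by complete-case per model, which reproduces the
  mechanism by which sample size shifts R^2 between single-SNP and
  multi-SNP models but makes exact parity with any external run of the
  same models untestable.
* Permutation p-values are add-one discrete; uniformity is asserted as
  super-uniformity bounds rather than a continuous KS test.
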