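# vernaliza

Vernalization-response traits and polygenic selection scans in structured,
highly selfing plant panels.

## The problem

In a selfing annual grass distributed across contrasting climates, flowering
time is gated by vernalization: a plant must experience enough cold before
it becomes competent to flower. Panels of such species are typically
structured into a few deeply diverged clades with essentially no gene flow
between them, which confounds every question one wants to ask: do
vernalization traits track the environment or just the clade of origin? Are
flowering-time genes under polygenic selection, or merely drifted apart by
bottlenecks? Is long-range linkage disequilibrium among candidate genes a
signal of co-selection or ordinary background LD in a selfer?

`vernaliza` implements the full inference chain for this setting, with an
explicit neutral calibration for each selection signal:

* **Trait extraction** — from replicated cold-treatment experiments
  (durations 2–10 weeks, 3 replicates, censoring allowed), four traits per
  accession: the minimum threshold duration of vernalization (MTD), days to
  flower at the MTD, the saturating duration beyond which extra cold gains
  nothing, and days to flower (from entry into cold) at saturation.
* **Constrained ordination** — redundancy analysis with Ezekiel-adjusted
  R², permutation tests, and `ordiR2step`-style double-stopping forward
  selection (admission requires improving adjusted R², permutation
  p ≤ `Pin`, and staying below the full-model adjusted R²).
* **F_ST** — per-SNP Weir–Cockerham variance components
  (θ = a/(a+b+c)), the multi-locus ratio-of-sums summary, and a neutral
  null from forward Wright–Fisher simulation of the split/bottleneck,
  no-migration selfing demography (default 100 replicates).
* **X^T^X** — a covariance-aware differentiation statistic
  (α' Ω⁻¹ α on standardized population frequency deviations, estimated in
  the deviation subspace), with the significance threshold taken as the
  0.99 quantile of a 100,000-locus pseudo-observed dataset (POD) drawn
  from the fitted neutral model.
* **LD** — genotype r², thinning, decay curves with bootstrap CIs, and an
  inter-chromosomal resampling null (50,000 resampled locus sets) against
  which the mean LD of a focal candidate-gene set is compared.
* **GWAS** — per-SNP linear mixed model with centered kinship and
  REML-profiled variance ratio, Benjamini–Hochberg FDR, and region calling
  by ≥ 4 significant markers per 8-kb window (4-kb step, merged).
* **Synthetic data** — a forward Wright–Fisher simulator (selfing, splits,
  bottlenecks, recombination, infinite-sites mutation, optional
  haplotype-block standing variation) plus generators for trait
  architectures, vernalization response curves and structure-correlated
  environments; this is the test bed that every statistic above is
  calibrated against.

See `vignettes/methods.Rmd` for the models, parameter defaults, numerical
decisions, and what the synthetic world does and does not establish.

## Worked example

Simulate a five-clade, three-lineage selfing panel (12 accessions per
clade), plant two causal loci — one partitioned between the A and B
lineages, one differentiated among clades within a lineage — run the
vernalization experiment with 2-day replicate noise, and push the result
through the pipeline:

```r
library(vernaliza)

clades <- c("A_East", "A_Italia", "B_East", "B_West", "C")
cfg <- demography_config(
  populations = data.frame(name = c("anc", clades), N = 120),
  splits = data.frame(
    parent = c("anc", "anc", "anc", "A_East", "B_East"),
    child = c("C", "A_East", "B_East", "A_Italia", "B_West"),
    generation = c(0, 0, 0, 10, 10)),
  selfing_rate = 0.99, generations = 30, n_sites = 800, n_chrom = 2,
  sample_sizes = setNames(rep(12, 5), clades),
  lineages = c(A_East = "A", A_Italia = "A", B_East = "B", B_West = "B",
               C = "C"),
  init = list(mode = "pool", n_seed = 6, rho = 0.002, mut = 0.002))

sim <- simulate_neutral(cfg, seed = 7)
ab  <- sim$pop_map[sim$pop_map$lineage %in% c("A", "B"), ]
fst <- weir_cockerham_fst(sim$gm, ab, level = "lineage")
pf  <- population_frequencies(sim$gm, sim$pop_map, level = "clade")
om  <- estimate_omega(pf$freqs, pf$n, seed = 8)
xtx <- xtx_statistic(pf$freqs, om)
causal <- c(which.max(fst$theta),
            which.max(ifelse(abs(fst$theta) < 0.05, xtx, NA)))

arch <- trait_architecture(
  causal_sites = data.frame(site = causal, mtd_weeks = c(2, 0),
                            sat_weeks = c(2, 0), dtf_days = c(0, 20)),
  baseline = c(mtd_weeks = 2, sat_weeks = 6, dtf_days = 30))
env <- env_model(
  clade_means = matrix(c(12, 14, 18, 17, 20, 800, 700, 450, 500, 380), 5, 2,
                       dimnames = list(clades, c("bio1", "bio12"))),
  within_sd = c(1.0, 40))

panel  <- simulate_panel(cfg, arch, env, noise_sd = 2, seed = 7)
traits <- extract_traits(panel$response, saturation_tol_days = 2)
head(traits[, 1:5], 3)
#>    sample_id mtd_weeks days_after_mtd saturation_weeks days_after_saturation
#> 1 A_East_001         6       98.00000               10                   140
#> 2 A_East_002         6       56.00000               10                   100
#> 3 A_East_003         6       59.33333               10                   100
```

A-lineage accessions carry the planted allele: MTD 6 weeks instead of 2,
saturation at 10 weeks, and correspondingly late flowering. Lineage-level
differentiation and the POD-calibrated X^T^X scan:

```r
fst_global(fst, n_boot = 200)$estimate
#> [1] 0.07087323

pod <- pod_calibrate(om, n_loci = 2e4, quantile = 0.99, seed = 9)
sprintf("POD 0.99 threshold: %.2f; outliers: %d of %d SNPs; causal XtX: %s",
        pod$threshold, sum(xtx > pod$threshold, na.rm = TRUE),
        sum(!is.na(xtx)), paste(round(xtx[causal], 1), collapse = ", "))
#> "POD 0.99 threshold: 17.25; outliers: 12 of 572 SNPs; causal XtX: 8.9, 21.7"
```

The genome-wide multi-locus F_ST between the lineages is low (0.071 —
drift under the bottlenecked demography), the POD threshold flags 12 of 572
scorable SNPs at the 1% level, and the clade-partitioned causal site
(X^T^X = 21.7) stands above the threshold while the purely A/B-partitioned
one (8.9) does not — clade-level contrasts carry the information here.
Finally, forward selection of trait predictors:

```r
keep <- !traits$never_flowered
forward_select(
  Y = traits$days_after_saturation[keep],
  candidates = data.frame(cluster = factor(panel$pop_map$clade[keep]),
                          bio1 = panel$environment$bio1[keep],
                          bio12 = panel$environment$bio12[keep]),
  Pin = 0.01, n_perm = 999, seed = 10)
#> forward selection trace (scope R2adj = 0.2218 ):
#>  variable cum_R2adj      AIC        F     p
#>   cluster 0.2166662 339.7703 5.079776 0.004
#> stopped: R2scope exceeded
```

The clade of origin enters (cumulative adjusted R² = 0.22, p = 0.004); the
bioclimatic variables, being proxies of the same structure in this world,
add nothing admissible beyond it — the scope rule then stops selection.
That entanglement of structure and environment is exactly the inferential
difficulty this pipeline is built to expose.

## Command line

A thin CLI ships in `inst/exec/vernaliza`:

```sh
vernaliza vcf-filter --in raw.vcf --out filtered.vcf --min-qual 20 --drop-het
vernaliza vcf-thin   --in filtered.vcf --out thin.vcf --bp 20000
vernaliza traits-extract --in response.tsv --out traits.tsv --tol-days 2
vernaliza fst  --in thin.vcf --pops samples.tsv --out fst.tsv
vernaliza gwas --in thin.vcf --pheno pheno.tsv --out assoc.tsv --peaks peaks.bed
```
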