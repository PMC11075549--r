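#' Per-SNP Weir-Cockerham F_ST between two populations
#'
#' Computes the Weir-Cockerham (1984) variance components per site — `a`
#' (among populations), `b` (among individuals within populations), `c`
#' (within individuals, from observed heterozygote counts) — from per-site
#' per-population sample sizes, allele frequencies and heterozygote
#' frequencies, and the per-site estimator `theta = a / (a + b + c)`. Sites
#' with fewer than two non-missing diploid calls in either population, and
#' sites monomorphic across both populations (`a + b + c == 0`), are
#' reported as NA and excluded from summaries.
#'
#' @param gm a [genotype_matrix()].
#' @param pop_map a [population_map()] whose grouping at `level` has exactly
#'   two groups (more raise an error; the statistic is pairwise).
#' @param level `"lineage"` (default, the A-vs-B contrast) or `"clade"`.
#' @return data.frame of class `fst_result`: `chrom`, `pos`, `a`, `b`, `c`,
#'   `theta`, `n1`, `n2`, `p1`, `p2`, with attribute `groups`.
#' @export
weir_cockerham_fst <- function(gm, pop_map, level = c("lineage", "clade")) {
  level <- match.arg(level)
  mp <- match_population_map(gm, pop_map, level = level)
  if (nlevels(mp$group) != 2L)
    stop("weir_cockerham_fst is pairwise: supply exactly 2 populations, got ",
         nlevels(mp$group))
  g1 <- mp$idx[mp$group == levels(mp$group)[1]]
  g2 <- mp$idx[mp$group == levels(mp$group)[2]]
  d1 <- gm$dosages[g1, , drop = FALSE]
  d2 <- gm$dosages[g2, , drop = FALSE]
  comp <- wc_components(d1, d2)
  out <- data.frame(chrom = gm$chrom, pos = gm$pos, a = comp$a, b = comp$b,
                    c = comp$c, theta = comp$theta,
                    n1 = comp$n1, n2 = comp$n2, p1 = comp$p1, p2 = comp$p2)
  attr(out, "groups") <- levels(mp$group)
  class(out) <- c("fst_result", "data.frame")
  out
}

# vectorized W&C (1984) components for two dosage matrices (rows = diploids)
wc_components <- function(d1, d2) {
  obs1 <- d1 != -1L; obs2 <- d2 != -1L
  n1 <- colSums(obs1); n2 <- colSums(obs2)
  p1 <- colSums(d1 * obs1) / (2 * n1)
  p2 <- colSums(d2 * obs2) / (2 * n2)
  h1 <- colSums(d1 == 1L) / n1
  h2 <- colSums(d2 == 1L) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  bad <- n1 < 2 | n2 < 2 | !is.finite(denom) | denom == 0
  theta <- ifelse(bad, NA_real_, a / denom)
  a[n1 < 2 | n2 < 2] <- NA_real_
  b[n1 < 2 | n2 < 2] <- NA_real_
  cc[n1 < 2 | n2 < 2] <- NA_real_
  list(a = a, b = b, c = cc, theta = theta, n1 = n1, n2 = n2, p1 = p1, p2 = p2)
}

#' Multi-locus F_ST from per-site variance components
#'
#' The Weir-Cockerham ratio-of-sums estimator
#' `sum(a) / sum(a + b + c)` over sites with defined components (the
#' "weighted" multi-locus combination the original authors prescribe),
#' with a bootstrap-over-loci standard error.
#'
#' @param fst an `fst_result` from [weir_cockerham_fst()].
#' @param n_boot bootstrap replicates over loci for the standard error
#'   (default 500; 0 skips it).
#' @param seed RNG seed for the bootstrap.
#' @return list with `estimate`, `se`, `n_sites`.
#' @export
fst_global <- function(fst, n_boot = 500, seed = 1L) {
  ok <- !is.na(fst$theta)
  a <- fst$a[ok]; denom <- (fst$a + fst$b + fst$c)[ok]
  est <- sum(a) / sum(denom)
  se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(i) {
      j <- sample.int(length(a), replace = TRUE)
      sum(a[j]) / sum(denom[j])
    }, numeric(1))
    se <- stats::sd(bs)
  }
  list(estimate = est, se = se, n_sites = sum(ok))
}

#' Neutral-simulation F_ST null distribution
#'
#' Runs the forward simulator `n_reps` times under the supplied neutral
#' demography, computes per-SNP Weir-Cockerham F_ST between the two sampled
#' populations for each replicate, and pools all defined per-SNP values into
#' one empirical null distribution, summarized by quantiles including the
#' third quartile and the top-5% cut used for outlier calling.
#'
#' @param config a [demography_config()] sampling exactly two populations.
#' @param n_reps number of simulation replicates (default 100).
#' @param seed integer seed; replicate r uses `seed + r`.
#' @param level grouping level passed to [weir_cockerham_fst()].
#' @return list of class `fst_null`: `theta` (pooled per-SNP values),
#'   `quantiles` (named, incl. `75%` and `95%`), `mean`, `n_reps`.
#' @export
fst_null_distribution <- function(config, n_reps = 100, seed = 1L,
                                  level = "clade") {
  if (length(config$sample_sizes) != 2L)
    stop("config must sample exactly the two compared populations")
  pooled <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    sim <- simulate_neutral(config, seed = seed + r)
    fst <- weir_cockerham_fst(sim$gm, sim$pop_map, level = level)
    pooled[[r]] <- fst$theta[!is.na(fst$theta)]
  }
  theta <- unlist(pooled)
  qs <- stats::quantile(theta, c(0.25, 0.5, 0.75, 0.95, 0.99))
  structure(list(theta = theta, quantiles = qs, mean = mean(theta),
                 n_reps = n_reps),
            class = "fst_null")
}

#' Flag top-tail F_ST outliers against an empirical distribution
#'
#' @param fst an `fst_result`.
#' @param null an `fst_null` from [fst_null_distribution()], or NULL to use
#'   the empirical distribution of `fst` itself.
#' @param top_fraction tail fraction (default 0.05).
#' @return logical vector (NA where theta undefined): theta strictly above
#'   the `1 - top_fraction` quantile of the reference distribution.
#' @export
fst_outliers <- function(fst, null = NULL, top_fraction = 0.05) {
  ref <- if (is.null(null)) fst$theta[!is.na(fst$theta)] else null$theta
  cut <- stats::quantile(ref, 1 - top_fraction, na.rm = TRUE)
  ifelse(is.na(fst$theta), NA, fst$theta > cut)
}
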