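# Genotype-correlation LD (r^2), decay curves with bootstrap confidence
# bands, and the inter-chromosomal resampling null used to test long-range
# LD among focal candidate-gene loci.

# standardized dosage matrix: missing calls mean-imputed per site, columns
# centered and scaled so that crossprod(Z)/(n-1) is the correlation matrix.
# Zero-variance sites get all-zero columns (their r2 is undefined).
standardize_dosages <- function(gm, sites = seq_len(n_sites(gm))) {
  d <- gm$dosages[, sites, drop = FALSE]
  d[d == -1L] <- NA
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  s <- apply(d, 2, stats::sd)
  Z <- sweep(d, 2, mu)
  ok <- s > 0
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2, s[ok], "/")
  Z[, !ok] <- 0
  attr(Z, "defined") <- ok
  Z
}

#' Squared genotype correlation (r^2) for site pairs
#'
#' `r^2` is the squared Pearson correlation of the two dosage vectors over
#' pairwise-complete accessions (both calls non-missing). Pairs with fewer
#' than two complete accessions or zero variance in either vector are
#' undefined and returned as NA.
#'
#' @param gm a [genotype_matrix()].
#' @param pairs 2-column integer matrix of site indices.
#' @return data.frame of class `ld_result`: `site_i`, `site_j`,
#'   `distance_bp` (NA for inter-chromosomal pairs), `interchrom`, `r2`.
#' @export
geno_r2 <- function(gm, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  d <- gm$dosages
  r2 <- vapply(seq_len(nrow(pairs)), function(k) {
    x <- d[, pairs[k, 1]]; y <- d[, pairs[k, 2]]
    ok <- x != -1L & y != -1L
    if (sum(ok) < 2) return(NA_real_)
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    r2 <- stats::cor(x, y)^2
    # snap floating-point noise so perfect LD is exactly representable
    if (r2 > 1 - 1e-12) r2 <- 1
    r2
  }, numeric(1))
  inter <- gm$chrom[pairs[, 1]] != gm$chrom[pairs[, 2]]
  out <- data.frame(site_i = pairs[, 1], site_j = pairs[, 2],
                    distance_bp = ifelse(inter, NA_integer_,
                                         abs(gm$pos[pairs[, 2]] - gm$pos[pairs[, 1]])),
                    interchrom = inter, r2 = r2)
  class(out) <- c("ld_result", "data.frame")
  out
}

#' LD decay curve with bootstrap confidence band
#'
#' Enumerates all intra-chromosomal site pairs within `max_dist_bp`, bins
#' them by distance into half-open bins `[lo, hi)` of width `bin_width_bp`,
#' and reports per bin the mean r^2 with a bootstrap percentile 95%
#' confidence interval of the mean. Thin the input first (one SNP per 20 kb
#' is the conventional preprocessing) and optionally apply a MAF filter.
#'
#' @param gm a [genotype_matrix()] (thinned upstream).
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_width_bp distance bin width.
#' @param min_maf optional minimum MAF applied before pairing (NULL = none).
#' @param n_boot bootstrap draws for the CI (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame: `bin_lo`, `bin_hi`, `n_pairs`, `mean_r2`, `ci_lo`,
#'   `ci_hi` (empty bins omitted).
#' @export
ld_decay <- function(gm, max_dist_bp, bin_width_bp, min_maf = NULL,
                     n_boot = 1000, seed = 1L) {
  if (!is.null(min_maf)) gm <- maf_filter(gm, min_maf)
  set.seed(seed)
  prs <- list()
  for (ch in unique(gm$chrom)) {
    i <- which(gm$chrom == ch)
    if (length(i) < 2) next
    pos <- gm$pos[i]
    # sliding right pointer: pairs within max_dist_bp
    for (a in seq_len(length(i) - 1)) {
      b <- which(pos > pos[a] & pos - pos[a] <= max_dist_bp)
      b <- b[b > a]
      if (length(b)) prs[[length(prs) + 1L]] <- cbind(i[a], i[b])
    }
  }
  if (!length(prs)) stop("no intra-chromosomal pairs within max_dist_bp")
  pairs <- do.call(rbind, prs)
  ld <- geno_r2(gm, pairs)
  ld <- ld[!is.na(ld$r2), , drop = FALSE]
  bin <- floor(ld$distance_bp / bin_width_bp)
  out <- lapply(sort(unique(bin)), function(bb) {
    v <- ld$r2[bin == bb]
    bs <- vapply(seq_len(n_boot), function(x)
      mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
    data.frame(bin_lo = bb * bin_width_bp, bin_hi = (bb + 1) * bin_width_bp,
               n_pairs = length(v), mean_r2 = mean(v),
               ci_lo = stats::quantile(bs, 0.025, names = FALSE),
               ci_hi = stats::quantile(bs, 0.975, names = FALSE))
  })
  do.call(rbind, out)
}

#' Sample inter-chromosomal r^2 over random loci
#'
#' Samples up to `n_loci` sites uniformly (restricted to `genic_regions`
#' when given), enumerates cross-chromosome pairs among them — capped at
#' `max_pairs` random pairs for memory — and computes r^2 per pair.
#'
#' @param gm a [genotype_matrix()] spanning >= 2 chromosomes.
#' @param n_loci number of loci to sample (default 1e5, capped at the
#'   available count).
#' @param genic_regions optional [gene_regions()] restricting eligible loci.
#' @param max_pairs cap on evaluated cross-chromosome pairs (default 2e6).
#' @param seed integer RNG seed.
#' @return list of class `interchrom_pool`: `loci` (site indices), `pairs`,
#'   `r2`, `capped`.
#' @export
interchrom_r2_sample <- function(gm, n_loci = 1e5, genic_regions = NULL,
                                 max_pairs = 2e6, seed = 1L) {
  if (length(unique(gm$chrom)) < 2) stop("need >= 2 chromosomes")
  set.seed(seed)
  eligible <- seq_len(n_sites(gm))
  if (!is.null(genic_regions)) {
    inreg <- rep(FALSE, n_sites(gm))
    for (k in seq_len(nrow(genic_regions)))
      inreg <- inreg | (gm$chrom == genic_regions$chrom[k] &
                        gm$pos > genic_regions$start[k] &
                        gm$pos <= genic_regions$end[k])
    eligible <- which(inreg)
  }
  loci <- if (length(eligible) > n_loci) sort(sample(eligible, n_loci))
          else eligible
  ch <- gm$chrom[loci]
  n_cross <- sum(outer(ch, ch, "!=")) / 2
  capped <- n_cross > max_pairs
  if (!capped) {
    cmb <- utils::combn(length(loci), 2)
    keep <- ch[cmb[1, ]] != ch[cmb[2, ]]
    pairs <- cbind(loci[cmb[1, keep]], loci[cmb[2, keep]])
  } else {
    i <- sample.int(length(loci), 2 * max_pairs, replace = TRUE)
    j <- sample.int(length(loci), 2 * max_pairs, replace = TRUE)
    ok <- ch[i] != ch[j]
    pairs <- unique(cbind(pmin(loci[i[ok]], loci[j[ok]]),
                          pmax(loci[i[ok]], loci[j[ok]])))
    if (nrow(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs), , drop = FALSE]
  }
  ld <- geno_r2(gm, pairs)
  structure(list(loci = loci, pairs = pairs, r2 = ld$r2, capped = capped,
                 gm = gm),
            class = "interchrom_pool")
}

#' Resampled-mean null for inter-chromosomal LD of a locus set
#'
#' Repeatedly draws `k` loci without replacement from the pool, computes the
#' mean r^2 over all cross-chromosome pairs among them, and returns the
#' 2.5/97.5 percentiles of the resampled means as the 95% CI (default
#' 50,000 resamples). In configuration-matched mode (the default when the
#' focal set is supplied) each resample reproduces the focal set's
#' per-chromosome locus counts, so the null matches the focal comparison's
#' pair geometry.
#'
#' @param pool an `interchrom_pool` from [interchrom_r2_sample()].
#' @param k set size (>= 2).
#' @param n_resamples number of resamples (default 50000).
#' @param seed integer RNG seed.
#' @param match_config optional character vector of chromosome labels (one
#'   per focal locus): resamples match these per-chromosome counts.
#' @return list of class `interchrom_null`: `k`, `n_resamples`, `means`,
#'   `ci_lo`, `ci_hi`, `mean_of_means`.
#' @export
resampled_mean_null <- function(pool, k, n_resamples = 50000, seed = 1L,
                                match_config = NULL) {
  if (k < 2) stop("k must be >= 2")
  if (length(pool$loci) < k) stop("pool smaller than k")
  set.seed(seed)
  gm <- pool$gm
  Z <- standardize_dosages(gm, pool$loci)
  ch <- gm$chrom[pool$loci]
  n <- nrow(Z)
  by_chrom <- split(seq_along(pool$loci), ch)
  use_config <- !is.null(match_config)
  if (use_config) {
    cfg <- table(match_config)
    if (!all(names(cfg) %in% names(by_chrom)))
      stop("match_config refers to chromosomes absent from the pool")
    if (any(cfg > lengths(by_chrom)[names(cfg)]))
      stop("pool too small on some chromosome for configuration matching")
  }
  means <- vapply(seq_len(n_resamples), function(i) {
    sel <- if (use_config) {
      unlist(lapply(names(cfg), function(cc)
        by_chrom[[cc]][sample.int(length(by_chrom[[cc]]), cfg[[cc]])]))
    } else sample.int(length(pool$loci), k)
    M <- crossprod(Z[, sel, drop = FALSE]) / (n - 1)
    cross <- outer(ch[sel], ch[sel], "!=")
    vals <- (M^2)[cross & upper.tri(cross)]
    if (!length(vals)) NA_real_ else mean(vals)
  }, numeric(1))
  means <- means[!is.na(means)]
  structure(list(k = k, n_resamples = n_resamples, means = means,
                 ci_lo = stats::quantile(means, 0.025, names = FALSE),
                 ci_hi = stats::quantile(means, 0.975, names = FALSE),
                 mean_of_means = mean(means)),
            class = "interchrom_null")
}

#' Mean LD of a focal locus set against the resampling null
#'
#' Computes the mean pairwise r^2 among the focal sites (cross-chromosome
#' pairs only in inter-chromosomal mode) and flags the set when its mean
#' exceeds the null's upper CI bound.
#'
#' @param gm a [genotype_matrix()].
#' @param focal_sites site indices of the focal loci (spanning >= 2
#'   chromosomes in inter-chromosomal mode).
#' @param null an `interchrom_null` from [resampled_mean_null()].
#' @param inter restrict to cross-chromosome pairs (default TRUE).
#' @return list: `mean_r2`, `n_pairs`, `outside_ci` (mean > `null$ci_hi`).
#' @export
focal_set_ld <- function(gm, focal_sites, null, inter = TRUE) {
  cmb <- utils::combn(focal_sites, 2)
  pairs <- cbind(cmb[1, ], cmb[2, ])
  if (inter) {
    keep <- gm$chrom[pairs[, 1]] != gm$chrom[pairs[, 2]]
    if (!any(keep)) stop("focal sites must span >= 2 chromosomes")
    pairs <- pairs[keep, , drop = FALSE]
  }
  r2 <- geno_r2(gm, pairs)$r2
  if (all(is.na(r2))) stop("all focal pairs undefined")
  m <- mean(r2, na.rm = TRUE)
  list(mean_r2 = m, n_pairs = sum(!is.na(r2)), outside_ci = m > null$ci_hi)
}

#' Collapse sites in perfect LD within a window
#'
#' Sliding-window greedy pruning in the spirit of plink's
#' `--indep-pairwise 50 5 1` with r^2 threshold 1: within each window of
#' `window` sites (advanced by `step`), one site of every pair with r^2 of
#' exactly 1 (up to `tol`) is removed, keeping the leftmost. Used to thin
#' perfectly redundant SNPs inside candidate genes before focal-SNP
#' selection.
#'
#' @param gm a [genotype_matrix()].
#' @param window window size in sites (default 50).
#' @param step window advance in sites (default 5).
#' @param tol tolerance below 1 still counted as perfect LD (default 1e-9).
#' @return the pruned [genotype_matrix()].
#' @export
ld_prune_perfect <- function(gm, window = 50L, step = 5L, tol = 1e-9) {
  keep <- rep(TRUE, n_sites(gm))
  for (ch in unique(gm$chrom)) {
    idx <- which(gm$chrom == ch)
    start <- 1L
    while (start <= length(idx)) {
      win <- idx[seq.int(start, min(start + window - 1L, length(idx)))]
      win <- win[keep[win]]
      if (length(win) > 1) {
        ld <- geno_r2(gm, t(utils::combn(win, 2)))
        drop <- unique(ld$site_j[!is.na(ld$r2) & ld$r2 >= 1 - tol &
                                   keep[ld$site_i]])
        keep[drop] <- FALSE
      }
      start <- start + step
    }
  }
  subset_sites(gm, keep)
}
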