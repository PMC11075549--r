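#' Site-level quality, missingness and heterozygosity filtering
#'
#' Retains sites that are biallelic (multi-allelic records are already
#' rejected at read time), have at most `max_missing_count` missing calls,
#' quality at least `min_qual` (inclusive), and — when `drop_het_sites` —
#' at most `max_het_count` heterozygous calls. In a highly selfing species
#' residual heterozygous calls flag duplicated sequence, so the default
#' removes any site with a single het call. The accession set is unchanged;
#' an empty result is allowed. All criteria are per-site and independent, so
#' the filter is idempotent and order-insensitive.
#'
#' @param gm a [genotype_matrix()].
#' @param max_missing_count maximum number of missing calls per site
#'   (default 200, the panel-scale convention).
#' @param min_qual minimum site quality, inclusive (default 20).
#' @param drop_het_sites apply the heterozygous-site screen (default TRUE).
#' @param max_het_count maximum heterozygous calls tolerated when
#'   `drop_het_sites` (default 0).
#' @return the filtered [genotype_matrix()].
#' @export
filter_variants <- function(gm, max_missing_count = 200L, min_qual = 20,
                            drop_het_sites = TRUE, max_het_count = 0L) {
  stopifnot(max_missing_count >= 0, max_het_count >= 0)
  d <- gm$dosages
  keep <- colSums(d == -1L) <= max_missing_count & gm$qual >= min_qual
  if (drop_het_sites) keep <- keep & colSums(d == 1L) <= max_het_count
  subset_sites(gm, keep)
}

#' Thin sites to a minimum physical spacing
#'
#' Greedy left-to-right scan per chromosome: a site is kept iff its position
#' is at least `min_spacing_bp` beyond the last kept site on the same
#' chromosome; the first site of every chromosome is always kept. This is the
#' "one SNP every 20 kb" pre-processing used before LD-decay estimation.
#'
#' @param gm a [genotype_matrix()] (positions sorted within chromosome).
#' @param min_spacing_bp minimum spacing in base pairs; 0 is the identity.
#' @return the thinned [genotype_matrix()].
#' @export
thin <- function(gm, min_spacing_bp) {
  stopifnot(min_spacing_bp >= 0)
  keep <- logical(n_sites(gm))
  for (ch in unique(gm$chrom)) {
    i <- which(gm$chrom == ch)
    last <- -Inf
    for (j in i) {
      if (gm$pos[j] - last >= min_spacing_bp) {
        keep[j] <- TRUE
        last <- gm$pos[j]
      }
    }
  }
  subset_sites(gm, keep)
}

#' Minor-allele-frequency filter
#'
#' Allele frequency is computed from non-missing dosages; a site is kept iff
#' `min(f, 1 - f) >= min_maf` (boundary inclusive). Sites with all calls
#' missing are removed with a message.
#'
#' @param gm a [genotype_matrix()].
#' @param min_maf minimum minor allele frequency in `[0, 0.5]`.
#' @return the filtered [genotype_matrix()].
#' @export
maf_filter <- function(gm, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  f <- allele_freq(gm)
  all_missing <- is.nan(f)
  if (any(all_missing))
    message(sum(all_missing), " site(s) with all calls missing removed")
  keep <- !all_missing & pmin(f, 1 - f) >= min_maf
  subset_sites(gm, keep)
}

#' Extract sites falling in candidate gene regions
#'
#' BED regions are 0-based half-open, VCF positions 1-based: a site at
#' position `p` lies in region `(start, end)` iff `start < p <= end`.
#' Overlapping regions assign a site to the first region in sort order, with
#' a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param regions a [gene_regions()].
#' @return a [genotype_matrix()] restricted to in-region sites, with an extra
#'   element `region` naming the containing region per kept site.
#' @export
extract_regions <- function(gm, regions) {
  ord <- order(regions$chrom, regions$start)
  regions <- regions[ord, , drop = FALSE]
  assigned <- rep(NA_character_, n_sites(gm))
  multi <- FALSE
  for (k in seq_len(nrow(regions))) {
    hit <- gm$chrom == regions$chrom[k] &
      gm$pos > regions$start[k] & gm$pos <= regions$end[k]
    multi <- multi || any(hit & !is.na(assigned))
    assigned[hit & is.na(assigned)] <- regions$name[k]
  }
  if (multi)
    warning("overlapping regions: sites assigned to the first region in sort order")
  keep <- !is.na(assigned)
  out <- subset_sites(gm, keep)
  out$region <- assigned[keep]
  out
}

#' Fraction of heterozygous calls
#'
#' The proportion of non-missing calls equal to 1, over all sites or over the
#' sites contained in `regions`. In a selfer this fraction, computed on a VCF
#' *not* screened for heterozygous sites, is a genome-integrity check:
#' residual hets flag collapsed duplications.
#'
#' @param gm a [genotype_matrix()].
#' @param regions optional [gene_regions()] restricting the scope.
#' @return a single number in `[0, 1]`.
#' @export
heterozygosity_fraction <- function(gm, regions = NULL) {
  if (!is.null(regions)) gm <- extract_regions(gm, regions)
  d <- gm$dosages
  n_obs <- sum(d != -1L)
  if (n_obs == 0L) stop("no non-missing calls in scope")
  sum(d == 1L) / n_obs
}
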