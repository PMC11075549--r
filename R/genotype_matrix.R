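#' Genotype matrix of dosage-coded biallelic sites
#'
#' The central genotype container: an accessions x sites integer matrix of
#' alternate-allele dosages with per-site chromosome, position and quality
#' metadata. Dosage codes are 0 (hom-ref), 1 (het), 2 (hom-alt) and -1
#' (missing call).
#'
#' @param dosages integer matrix, accessions in rows, sites in columns,
#'   entries in \{0, 1, 2, -1\}.
#' @param chrom character vector of per-site chromosome labels.
#' @param pos integer vector of 1-based per-site positions, strictly
#'   increasing within each chromosome.
#' @param qual numeric vector of per-site quality scores (default `Inf`,
#'   i.e. "never filtered on quality").
#' @param sample_ids unique per-accession identifiers (default `acc1..accN`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `chrom`, `pos`, `qual`, `sample_ids`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0L, 2L), 2, 1), chrom = "Bd1", pos = 100L)
#' n_sites(gm)
#' @export
genotype_matrix <- function(dosages, chrom, pos, qual = NULL, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  L <- ncol(dosages)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (is.null(qual)) qual <- rep(Inf, L)
  qual <- as.numeric(qual)
  if (is.null(sample_ids)) sample_ids <- paste0("acc", seq_len(nrow(dosages)))
  sample_ids <- as.character(sample_ids)
  gm <- structure(
    list(dosages = dosages, chrom = chrom, pos = pos, qual = qual,
         sample_ids = sample_ids),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  L <- ncol(gm$dosages)
  if (length(gm$chrom) != L || length(gm$pos) != L || length(gm$qual) != L)
    stop("site metadata length does not match number of dosage columns")
  if (length(gm$sample_ids) != nrow(gm$dosages))
    stop("sample_ids length does not match number of dosage rows")
  if (anyDuplicated(gm$sample_ids))
    stop("sample_ids must be unique")
  bad <- !(gm$dosages %in% c(0L, 1L, 2L, -1L))
  if (any(bad))
    stop("dosage codes restricted to {0, 1, 2, -1}")
  if (L > 1L) {
    same <- gm$chrom[-1L] == gm$chrom[-L]
    if (any(same & diff(gm$pos) <= 0L))
      stop("pos must be strictly increasing within each chromosome")
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d sites on %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$chrom))))
  miss <- mean(x$dosages == -1L)
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
n_sites <- function(gm) ncol(gm$dosages)

#' @rdname genotype_matrix
#' @export
n_accessions <- function(gm) nrow(gm$dosages)

# site subset keeping metadata in step; used by every filter
subset_sites <- function(gm, keep) {
  genotype_matrix(gm$dosages[, keep, drop = FALSE], gm$chrom[keep],
                  gm$pos[keep], gm$qual[keep], gm$sample_ids)
}

subset_accessions <- function(gm, keep) {
  genotype_matrix(gm$dosages[keep, , drop = FALSE], gm$chrom, gm$pos,
                  gm$qual, gm$sample_ids[keep])
}

#' Per-site alternate allele frequencies
#'
#' Frequencies are computed from non-missing calls only (sum of dosages over
#' twice the number of non-missing calls). Sites with all calls missing get
#' `NaN`.
#'
#' @param gm a [genotype_matrix()].
#' @return numeric vector of length `n_sites(gm)`.
#' @export
allele_freq <- function(gm) {
  d <- gm$dosages
  obs <- d != -1L
  alt <- colSums(d * obs)
  n <- colSums(obs)
  alt / (2 * n)
}

#' Population map: accession to clade and lineage assignment
#'
#' @param sample_id accession identifiers.
#' @param clade clade label per accession (the population unit for
#'   differentiation statistics).
#' @param lineage lineage label per accession (coarser grouping; defaults to
#'   the clade labels).
#' @return data.frame of class `population_map` with columns `sample_id`,
#'   `clade`, `lineage`.
#' @export
population_map <- function(sample_id, clade, lineage = clade) {
  pm <- data.frame(sample_id = as.character(sample_id),
                   clade = as.character(clade),
                   lineage = as.character(lineage),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pm$sample_id)) stop("duplicated sample_id in population map")
  class(pm) <- c("population_map", "data.frame")
  pm
}

#' Read a tab-separated sample map (sample_id, clade, lineage)
#'
#' @param path path to a TSV with columns `sample_id`, `clade` and optionally
#'   `lineage`.
#' @return a [population_map()].
#' @export
read_population_map <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "clade") %in% names(df)))
    stop("sample map needs columns sample_id, clade")
  if (is.null(df$lineage)) df$lineage <- df$clade
  population_map(df$sample_id, df$clade, df$lineage)
}

#' Write a population map as TSV
#' @param pm a [population_map()].
#' @param path output path.
#' @export
write_population_map <- function(pm, path) {
  data.table::fwrite(as.data.frame(pm), path, sep = "\t")
  invisible(path)
}

# check a population map against a genotype matrix; returns clade factor
# aligned with gm$sample_ids (restricted to mapped accessions)
match_population_map <- function(gm, pm, level = c("clade", "lineage")) {
  level <- match.arg(level)
  missing_acc <- setdiff(pm$sample_id, gm$sample_ids)
  if (length(missing_acc))
    stop("population map refers to accessions absent from the genotype matrix: ",
         paste(utils::head(missing_acc, 5), collapse = ", "))
  idx <- match(pm$sample_id, gm$sample_ids)
  grp <- factor(pm[[level]])
  if (nlevels(grp) < 2)
    stop("need >= 2 populations for differentiation statistics")
  list(idx = idx, group = grp)
}

#' Candidate gene regions (BED-style, 0-based half-open)
#'
#' @param chrom chromosome labels.
#' @param start 0-based start coordinates.
#' @param end end coordinates (exclusive); must satisfy `start < end`.
#' @param name unique region names.
#' @return data.frame of class `gene_regions`.
#' @export
gene_regions <- function(chrom, start, end, name) {
  gr <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   stringsAsFactors = FALSE)
  if (any(gr$start >= gr$end)) stop("gene regions require start < end")
  if (anyDuplicated(gr$name)) stop("gene region names must be unique")
  class(gr) <- c("gene_regions", "data.frame")
  gr
}

#' Read a BED3+name file of candidate gene regions
#' @param path path to a BED file (chrom, start, end, name; no header).
#' @return a [gene_regions()].
#' @export
read_gene_regions <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(df) < 4) stop("BED file needs 4 columns: chrom, start, end, name")
  gene_regions(df[[1]], df[[2]], df[[3]], df[[4]])
}
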