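#' Read diploid GT calls from a VCF file
#'
#' A deliberately narrow VCFv4.x reader for the one field this pipeline
#' consumes: the per-sample GT genotype. `0/0` maps to dosage 0, `0/1` or
#' `1/0` to 1, `1/1` to 2 and `./.` to -1; phased separators (`|`) are
#' treated as unphased. Multi-allelic records are permitted on input and
#' dropped (see `drop_multiallelic`), mirroring a `--max-alleles 2` filter:
#' they are rejected whole, never decomposed. Site order is preserved.
#'
#' @param path path to an uncompressed or gzipped VCF file.
#' @param drop_multiallelic drop records whose ALT holds more than one
#'   allele (default TRUE). With FALSE, such records raise an error.
#' @return a [genotype_matrix()].
#' @seealso [write_vcf()] for the inverse operation.
#' @export
read_vcf <- function(path, drop_multiallelic = TRUE) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L)
    stop("malformed VCF header: expected exactly one #CHROM line in ", path)
  header <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10L)
    stop("VCF has no sample columns (line ", hdr, ")")
  samples <- header[-(1:9)]
  body_idx <- seq.int(hdr + 1L, length.out = length(lines) - hdr)
  body <- lines[body_idx]
  body <- body[nzchar(body)]
  n_samp <- length(samples)

  if (!length(body)) {
    return(genotype_matrix(matrix(integer(0), n_samp, 0), character(0),
                           integer(0), numeric(0), samples))
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  len <- lengths(fields)
  if (any(len != 9L + n_samp)) {
    bad <- which(len != 9L + n_samp)[1L]
    stop("ragged VCF record at line ", hdr + bad, ": expected ",
         9L + n_samp, " fields, found ", len[bad])
  }
  rec <- matrix(unlist(fields), ncol = 9L + n_samp, byrow = TRUE)

  multi <- grepl(",", rec[, 5L], fixed = TRUE)
  if (any(multi)) {
    if (!drop_multiallelic)
      stop("multi-allelic record at line ", hdr + which(multi)[1L])
    rec <- rec[!multi, , drop = FALSE]
  }
  if (!nrow(rec)) {
    return(genotype_matrix(matrix(integer(0), n_samp, 0), character(0),
                           integer(0), numeric(0), samples))
  }

  gt_field <- rec[, 10:(9L + n_samp), drop = FALSE]
  # GT is the first colon-separated entry; normalize | to /
  gt <- sub(":.*$", "", gt_field)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
            "./." = -1L, "." = -1L)
  dos <- code[gt]
  if (anyNA(dos)) {
    bad <- which(is.na(dos))[1L]
    site <- (bad - 1L) %/% n_samp + 1L
    stop("unparseable GT '", gt[bad], "' at VCF data record ", site)
  }
  dos <- matrix(dos, nrow = nrow(rec), ncol = n_samp)
  qual <- suppressWarnings(as.numeric(rec[, 6L]))
  qual[rec[, 6L] == "."] <- Inf

  genotype_matrix(t(dos), chrom = rec[, 1L], pos = as.integer(rec[, 2L]),
                  qual = qual, sample_ids = samples)
}

#' Write a genotype matrix as a GT-only VCFv4.2 file
#'
#' Emits one FORMAT field (GT) with unphased separators; dosage 1 is always
#' written as the canonical het `0/1`, missing as `./.`. `read_vcf()` applied
#' to the output recovers the input matrix exactly (dosages, chrom, pos,
#' qual, sample ids).
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open '", path, "' for writing"))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=vernaliza",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")
  ), con)
  L <- n_sites(gm)
  if (L == 0L) return(invisible(path))
  gt_map <- c(`-1` = "./.", `0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_map[as.character(gm$dosages)], nrow = nrow(gm$dosages))
  qual <- ifelse(is.infinite(gm$qual), ".", sprintf("%.17g", gm$qual))
  lines <- paste(gm$chrom, gm$pos, ".", "A", "T", qual, "PASS", ".", "GT",
                 apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
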