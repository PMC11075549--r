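test_that("read_vcf maps GT codes and preserves site order", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t30\tPASS\t.\tGT\t0/0\t1/1",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT\t0|1\t./.",
    "chr1\t300\t.\tG\tC,A\t10\tPASS\t.\tGT\t1/2\t0/0",
    "chr2\t50\t.\tT\tA\t25\tPASS\t.\tGT\t1/0\t1/1"
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- read_vcf(f)
  # multi-allelic record dropped whole, never decomposed
  expect_equal(n_sites(gm), 3L)
  expect_equal(gm$dosages, matrix(c(0L, 2L, 1L, -1L, 1L, 2L), 2, 3),
               ignore_attr = TRUE)
  expect_equal(gm$pos, c(100L, 200L, 50L))
  expect_equal(gm$sample_ids, c("s1", "s2"))
  expect_true(is.infinite(gm$qual[2]))  # missing QUAL never filtered out
})

test_that("read_vcf names the offending line on ragged records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t30\tPASS\t.\tGT\t0/0\textra"
  ), f)
  expect_error(read_vcf(f), "line 2")
  writeLines("no header here", f)
  expect_error(read_vcf(f), "header")
})

test_that("write_vcf/read_vcf round-trip is lossless and het is canonical", {
  gm <- toy_gm(n = 10, L = 10, seed = 42, miss = 0.15,
               chrom = rep(c("chr1", "chr2"), each = 5))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  back <- read_vcf(f)
  expect_identical(back$dosages, gm$dosages)
  expect_identical(back$chrom, gm$chrom)
  expect_identical(back$pos, gm$pos)
  expect_equal(back$qual, gm$qual)
  expect_identical(back$sample_ids, gm$sample_ids)
  lines <- readLines(f)
  expect_false(any(grepl("1/0", lines, fixed = TRUE)))
  # empty matrix -> header-only VCF
  f2 <- withr::local_tempfile(fileext = ".vcf")
  empty <- genotype_matrix(matrix(integer(0), 3, 0), character(0), integer(0),
                           sample_ids = c("a", "b", "c"))
  write_vcf(empty, f2)
  expect_equal(n_sites(read_vcf(f2)), 0L)
  expect_equal(read_vcf(f2)$sample_ids, c("a", "b", "c"))
})

test_that("read_vcf agrees with bcftools on a fixture", {
  skip_if(Sys.which("bcftools") == "", "bcftools not on PATH")
  gm <- toy_gm(n = 8, L = 12, seed = 7, miss = 0.2)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  out <- system2("bcftools", c("query", "-f", shQuote("[%GT ]\\n"), f),
                 stdout = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L, "./." = -1L)
  ora <- t(vapply(strsplit(trimws(out), " "),
                  function(x) unname(code[x]), integer(8)))
  expect_equal(unname(gm$dosages), unname(t(ora)))
})

test_that("genotype_matrix enforces its invariants", {
  expect_error(genotype_matrix(matrix(3L, 1, 1), "c", 1L), "dosage codes")
  expect_error(genotype_matrix(matrix(0L, 1, 2), c("c", "c"), c(5L, 5L)),
               "strictly increasing")
  expect_error(genotype_matrix(matrix(0L, 2, 1), "c", 1L,
                               sample_ids = c("a", "a")), "unique")
  # same position on different chromosomes is fine
  expect_silent(genotype_matrix(matrix(0L, 1, 2), c("c1", "c2"), c(5L, 5L)))
})

test_that("filter_variants applies inclusive boundaries per criterion", {
  # 5 sites: qual 19 vs 20 boundary, missing-count boundary, het counts
  d <- rbind(c(0L, 0L, -1L, 1L, 0L),
             c(0L, 2L, -1L, 0L, 1L),
             c(2L, 2L, 0L, 0L, 0L))
  gm <- genotype_matrix(d, rep("c1", 5), 1:5 * 10L,
                        qual = c(19, 20, 35, 35, 35))
  out <- filter_variants(gm, max_missing_count = 1, min_qual = 20,
                         drop_het_sites = TRUE, max_het_count = 0)
  # site1 qual<20; site3 2 missing > 1; sites 4,5 have a het call
  expect_equal(out$pos, 20L)
  # brute-force re-check of each per-site criterion
  keep_oracle <- vapply(1:5, function(j) {
    col <- d[, j]
    gm$qual[j] >= 20 && sum(col == -1L) <= 1 && sum(col == 1L) <= 0
  }, logical(1))
  expect_equal(gm$pos[keep_oracle], out$pos)
  # tolerant het count keeps single-het sites
  out2 <- filter_variants(gm, max_missing_count = 1, min_qual = 20,
                          drop_het_sites = TRUE, max_het_count = 1)
  expect_equal(out2$pos, c(20L, 40L, 50L))
  # filters are idempotent
  expect_identical(filter_variants(out, 1, 20, TRUE, 0)$dosages, out$dosages)
})

test_that("thin keeps the greedy >= spacing set per chromosome", {
  gm <- genotype_matrix(matrix(0L, 2, 5),
                        chrom = c("c1", "c1", "c1", "c2", "c2"),
                        pos = c(100L, 15000L, 25000L, 100L, 19000L))
  out <- thin(gm, 20000)
  expect_equal(out$pos, c(100L, 25000L, 100L))
  expect_equal(out$chrom, c("c1", "c1", "c2"))
  # spacing 0 is the identity; thinning is idempotent
  expect_identical(thin(gm, 0)$pos, gm$pos)
  expect_identical(thin(out, 20000)$pos, out$pos)
})

test_that("maf_filter computes frequency from non-missing calls", {
  # 10 accessions, one alt allele: f = 0.05 kept at boundary
  d1 <- matrix(c(1L, rep(0L, 9)), 10, 1)
  gm1 <- genotype_matrix(d1, "c", 1L)
  expect_equal(n_sites(maf_filter(gm1, 0.05)), 1L)
  # f = 0.04: removed (25 accessions, 2 alt alleles)
  d2 <- matrix(c(2L, rep(0L, 24)), 25, 1)
  expect_equal(n_sites(maf_filter(genotype_matrix(d2, "c", 1L), 0.05)), 0L)
  # missing calls excluded from the denominator
  gm3 <- toy_gm(n = 20, L = 30, seed = 3, miss = 0.3)
  out <- maf_filter(gm3, 0.1)
  keep_oracle <- vapply(seq_len(30), function(j) {
    col <- gm3$dosages[, j]
    col <- col[col != -1L]
    f <- sum(col) / (2 * length(col))
    length(col) > 0 && min(f, 1 - f) >= 0.1
  }, logical(1))
  expect_equal(out$pos, gm3$pos[keep_oracle])
})

test_that("extract_regions converts BED half-open to VCF 1-based", {
  gm <- genotype_matrix(matrix(0L, 1, 10), rep("c1", 10), (1:10) * 33L)
  gr <- gene_regions("c1", 99, 200, "gene1")
  out <- extract_regions(gm, gr)
  expect_equal(out$pos, c(132L, 165L, 198L))
  # explicit boundaries: pos 100 in (99, 200], pos 99 out
  gm2 <- genotype_matrix(matrix(0L, 1, 2), c("c1", "c1"), c(99L, 100L))
  out2 <- extract_regions(gm2, gr)
  expect_equal(out2$pos, 100L)
  expect_equal(out2$region, "gene1")
  # 3-region toy against brute-force interval membership
  gr3 <- gene_regions(rep("c1", 3), c(0, 120, 240), c(40, 200, 300),
                      c("g1", "g2", "g3"))
  out3 <- extract_regions(gm, gr3)
  member <- vapply(gm$pos, function(p)
    any(gr3$start < p & p <= gr3$end), logical(1))
  expect_equal(out3$pos, gm$pos[member])
  # overlap warns and assigns first in sort order
  gr4 <- gene_regions(c("c1", "c1"), c(0, 30), c(66, 99), c("ga", "gb"))
  expect_warning(out4 <- extract_regions(gm, gr4), "overlap")
  expect_equal(out4$region[out4$pos == 33L], "ga")
})

test_that("heterozygosity_fraction counts hets over non-missing calls", {
  gm <- genotype_matrix(matrix(c(0L, 2L, 0L, 2L), 2, 2), c("c1", "c1"),
                        c(1L, 2L))
  expect_equal(heterozygosity_fraction(gm), 0)
  # 1 het among 20 non-missing
  d <- matrix(0L, 4, 5); d[1, 1] <- 1L
  expect_equal(heterozygosity_fraction(
    genotype_matrix(d, rep("c", 5), 1:5)), 0.05)
  # missing calls excluded from the denominator: 1 het, 18 non-missing
  d[2, 1] <- -1L; d[3, 2] <- -1L
  expect_equal(heterozygosity_fraction(
    genotype_matrix(d, rep("c", 5), 1:5)), 1 / 18)
  empty <- genotype_matrix(matrix(-1L, 2, 1), "c", 1L)
  expect_error(heterozygosity_fraction(empty), "non-missing")
})

test_that("population map and gene regions validate their contracts", {
  pm <- population_map(c("a", "b"), c("X", "Y"))
  expect_equal(pm$lineage, c("X", "Y"))
  expect_error(population_map(c("a", "a"), c("X", "Y")), "duplicated")
  expect_error(gene_regions("c", 10, 10, "g"), "start < end")
  expect_error(gene_regions(c("c", "c"), c(1, 5), c(4, 9), c("g", "g")),
               "unique")
  gm <- toy_gm(n = 2, L = 2, seed = 1)
  bad <- population_map(c("acc1", "ghost"), c("X", "Y"))
  expect_error(weir_cockerham_fst(gm, bad), "absent")
})

test_that("sample map and BED round-trip through TSV readers", {
  pm <- population_map(c("a1", "a2", "a3"), c("A_East", "B_West", "C"),
                       c("A", "B", "C"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_population_map(pm, f)
  expect_equal(as.data.frame(read_population_map(f)), as.data.frame(pm))
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tVRN1", "chr2\t0\t50\tFTL1"), bed)
  gr <- read_gene_regions(bed)
  expect_equal(gr$name, c("VRN1", "FTL1"))
  expect_equal(gr$start, c(99L, 0L))
})
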