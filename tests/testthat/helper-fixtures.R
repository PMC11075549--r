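# shared fixtures and independent oracles, built in code at test time

# small random genotype matrix
toy_gm <- function(n = 6, L = 10, seed = 1, miss = 0.1,
                   chrom = NULL, pos = NULL, qual = NULL) {
  set.seed(seed)
  d <- matrix(sample(c(0L, 1L, 2L), n * L, replace = TRUE), n, L)
  if (miss > 0) d[stats::runif(n * L) < miss] <- -1L
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) {
    pos <- integer(L)
    for (ch in unique(chrom)) {
      i <- chrom == ch
      pos[i] <- sort(sample.int(1e6, sum(i)))
    }
  }
  if (is.null(qual)) qual <- round(stats::runif(L, 10, 60), 2)
  genotype_matrix(d, chrom, pos, qual)
}

# independent transcription of the Weir & Cockerham (1984) two-population
# per-locus component formulas, scalar arithmetic only (the oracle; kept
# deliberately naive and separate from the vectorized implementation)
wc_oracle_site <- function(geno1, geno2) {
  g1 <- geno1[geno1 != -1]
  g2 <- geno2[geno2 != -1]
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2 || n2 < 2) return(list(a = NA, b = NA, c = NA, theta = NA))
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
    ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  th <- if (a + b + cc == 0) NA else a / (a + b + cc)
  list(a = a, b = b, c = cc, theta = th)
}

# brute-force O(n^2) Kendall tau-b oracle
kendall_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# a noiseless vernalization response world whose true traits sit exactly on
# the design/scoring grid, for round-trip identity checks
grid_architecture <- function() {
  trait_architecture(
    causal_sites = data.frame(site = c(1L, 2L),
                              mtd_weeks = c(2, 0), sat_weeks = c(2, 0),
                              dtf_days = c(0, 6)),
    baseline = c(mtd_weeks = 2, sat_weeks = 6, dtf_days = 30),
    slope_days_per_week = 7)
}

# default five-clade, three-lineage demography at test scale
clade_config <- function(n_sites = 800L, generations = 30L,
                         sample_per_clade = 12L, selfing = 0.99) {
  clades <- c("A_East", "A_Italia", "B_East", "B_West", "C")
  demography_config(
    populations = data.frame(name = c("anc", clades), N = 120L),
    splits = data.frame(parent = c("anc", "anc", "anc", "A_East", "B_East"),
                        child = c("C", "A_East", "B_East", "A_Italia", "B_West"),
                        generation = c(0L, 0L, 0L, 10L, 10L)),
    selfing_rate = selfing, generations = generations, n_sites = n_sites,
    recomb = 1e-3, n_chrom = 2L, spacing_bp = 1000L,
    sample_sizes = stats::setNames(rep(sample_per_clade, 5), clades),
    lineages = c(A_East = "A", A_Italia = "A", B_East = "B", B_West = "B",
                 C = "C", anc = "A"),
    init = list(mode = "pool", n_seed = 6, rho = 0.002, mut = 0.002,
                block_sites = 15))
}
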