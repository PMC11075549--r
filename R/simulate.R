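#' Demography configuration for the forward simulator
#'
#' Describes a split/bottleneck demography with partial selfing and no
#' migration, the neutral scenario used to calibrate differentiation
#' statistics. Populations evolve as discrete-generation Wright-Fisher
#' units; children are founded by copying individuals from their parent at
#' the split generation (without replacement when the parent is large
#' enough, so a same-size split is an exact copy and divergence starts at
#' the split itself).
#'
#' @param populations data.frame with columns `name`, `N` (diploid size) and
#'   optionally `bn_start`, `bn_end`, `bn_size` (a bottleneck: size `bn_size`
#'   for generations in `[bn_start, bn_end)`).
#' @param splits data.frame with columns `parent`, `child`, `generation`
#'   (may be empty/NULL). A child must be declared in `populations`.
#' @param selfing_rate per-offspring probability of self-fertilization in
#'   `[0, 1]`. Default 0.99: the study system is a highly selfing annual and
#'   its exact rate is not printed; near-complete selfing is the standard
#'   assumption.
#' @param generations total number of generations simulated.
#' @param mutation_rate per-site per-generation mutation probability
#'   (0 -> 1 flips; an infinite-sites approximation, recurrent hits being
#'   negligible at the rates used).
#' @param n_sites number of sites on the simulated map.
#' @param recomb per-adjacent-site crossover probability within a
#'   chromosome; chromosome boundaries recombine freely.
#' @param sample_sizes named integer vector: diploid individuals sampled per
#'   population at the end (populations absent from it are not sampled).
#' @param n_chrom number of equally sized chromosomes the sites are split
#'   across (default 1).
#' @param spacing_bp physical spacing between adjacent sites (default 1000).
#' @param lineages optional named character vector mapping population name to
#'   lineage label (defaults to the population name).
#' @param init ancestral standing variation for root populations, a list with
#'   `mode` one of:
#'   * `"monomorphic"` — all-reference start; variation from mutation only.
#'   * `"uniform"` — per-site ancestral frequencies drawn uniformly from
#'     `[init$lo, init$hi]`, alleles independent across sites (no initial LD).
#'   * `"sfs"` — frequencies from the neutral 1/x spectrum on
#'     `[init$lo, init$hi]`, alleles independent across sites.
#'   * `"pool"` — a haplotype-copying pool: `init$n_seed` seed haplotypes
#'     with blocky allele patterns (mean run length `init$block_sites`
#'     sites), recursively copied Li-and-Stephens-style with per-boundary
#'     switch probability `init$rho` and flip probability `init$mut`. This
#'     equips the standing variation with haplotype-block local LD (the
#'     selfing-panel regime) without a long burn-in.
#' @return a list of class `demography_config`.
#' @export
demography_config <- function(populations, splits = NULL, selfing_rate = 0.99,
                              generations = 100L, mutation_rate = 0,
                              n_sites = 1000L, recomb = 1e-3,
                              sample_sizes = NULL, n_chrom = 1L,
                              spacing_bp = 1000L, lineages = NULL,
                              init = list(mode = "sfs", lo = 0.05, hi = 0.95)) {
  populations <- as.data.frame(populations)
  stopifnot(all(c("name", "N") %in% names(populations)))
  if (any(populations$N < 2)) stop("population sizes must be >= 2")
  if (!is.null(splits)) {
    splits <- as.data.frame(splits)
    stopifnot(all(c("parent", "child", "generation") %in% names(splits)))
    splits <- splits[order(splits$generation), , drop = FALSE]
    if (!all(splits$child %in% populations$name))
      stop("every split child must be declared in populations")
  }
  if (selfing_rate < 0 || selfing_rate > 1) stop("selfing_rate must be in [0, 1]")
  if (is.null(sample_sizes)) {
    sample_sizes <- stats::setNames(pmin(populations$N, 20L), populations$name)
  }
  if (is.null(lineages))
    lineages <- stats::setNames(populations$name, populations$name)
  structure(list(populations = populations, splits = splits,
                 selfing_rate = selfing_rate, generations = as.integer(generations),
                 mutation_rate = mutation_rate, n_sites = as.integer(n_sites),
                 recomb = recomb, sample_sizes = sample_sizes,
                 n_chrom = as.integer(n_chrom), spacing_bp = as.integer(spacing_bp),
                 lineages = lineages, init = init),
            class = "demography_config")
}

# site map: chromosome labels and positions for the simulated lattice
sim_site_map <- function(config) {
  L <- config$n_sites
  per <- ceiling(L / config$n_chrom)
  chrom_idx <- rep(seq_len(config$n_chrom), each = per)[seq_len(L)]
  pos <- (seq_len(L) - (chrom_idx - 1L) * per) * config$spacing_bp
  list(chrom = paste0("chr", chrom_idx), pos = as.integer(pos),
       # per-boundary crossover probability; free recombination across chroms
       rvec = ifelse(chrom_idx[-1L] == chrom_idx[-L], config$recomb, 0.5))
}

# gametes from `parents` (individual indices into hap, a 2N x L 0/1 matrix)
# rvec: per-boundary crossover probabilities, length L-1
sim_gametes <- function(hap, parents, rvec) {
  L <- ncol(hap)
  M <- length(parents)
  h1 <- hap[2L * parents - 1L, , drop = FALSE]
  if (L == 1L) {
    pick <- stats::rbinom(M, 1L, 0.5)
    return(h1 * (1L - pick) + hap[2L * parents, , drop = FALSE] * pick)
  }
  h2 <- hap[2L * parents, , drop = FALSE]
  sw <- matrix(stats::rbinom(M * L, 1L, rep(c(0.5, rvec), each = M)), M, L)
  mask <- t(apply(sw, 1L, cumsum)) %% 2L
  h1 * (1L - mask) + h2 * mask
}

# one WF generation with partial selfing; returns haplotypes of N_next offspring
sim_next_generation <- function(hap, n_next, selfing_rate, rvec, mu) {
  n_cur <- nrow(hap) %/% 2L
  mothers <- sample.int(n_cur, n_next, replace = TRUE)
  outcross <- stats::runif(n_next) >= selfing_rate
  fathers <- mothers
  if (any(outcross))
    fathers[outcross] <- sample.int(n_cur, sum(outcross), replace = TRUE)
  g1 <- sim_gametes(hap, mothers, rvec)
  g2 <- sim_gametes(hap, fathers, rvec)
  nxt <- matrix(0L, 2L * n_next, ncol(hap))
  nxt[seq(1L, 2L * n_next, 2L), ] <- g1
  nxt[seq(2L, 2L * n_next, 2L), ] <- g2
  if (mu > 0) {
    nm <- stats::rpois(1L, 2 * n_next * ncol(hap) * mu)
    if (nm > 0) {
      idx <- cbind(sample.int(2L * n_next, nm, replace = TRUE),
                   sample.int(ncol(hap), nm, replace = TRUE))
      nxt[idx] <- 1L
    }
  }
  nxt
}

# ancestral standing variation (2N haplotypes) according to config$init
sim_init_haplotypes <- function(n_dip, L, init, rvec) {
  mode <- if (is.null(init$mode)) "monomorphic" else init$mode
  n_hap <- 2L * n_dip
  if (mode == "monomorphic") return(matrix(0L, n_hap, L))
  if (mode %in% c("uniform", "sfs")) {
    lo <- if (is.null(init$lo)) 0.05 else init$lo
    hi <- if (is.null(init$hi)) 0.95 else init$hi
    p0 <- if (mode == "uniform") stats::runif(L, lo, hi)
          else exp(stats::runif(L, log(lo), log(hi)))  # density ~ 1/x
    return(matrix(stats::rbinom(n_hap * L, 1L, rep(p0, each = n_hap)), n_hap, L))
  }
  if (mode == "pool") {
    n_seed <- if (is.null(init$n_seed)) 4L else init$n_seed
    rho <- if (is.null(init$rho)) 5e-4 else init$rho
    mut <- if (is.null(init$mut)) 2e-3 else init$mut
    lo <- if (is.null(init$lo)) 0.1 else init$lo
    hi <- if (is.null(init$hi)) 0.9 else init$hi
    block_sites <- if (is.null(init$block_sites)) 20 else init$block_sites
    H <- matrix(0L, n_hap, L)
    n_seed <- min(n_seed, n_hap)
    # seed haplotypes carry blocky allele patterns (mean run length
    # block_sites, reset at chromosome breaks): adjacent sites in a block
    # share one pattern across seeds, the haplotype-block structure typical
    # of a selfer; mosaic copying and flips below then perturb it
    new_block <- c(TRUE, stats::runif(L - 1L) < 1 / block_sites | rvec >= 0.5)
    block_id <- cumsum(new_block)
    n_blk <- max(block_id)
    p_blk <- exp(stats::runif(n_blk, log(lo), log(hi)))
    pat <- matrix(stats::rbinom(n_seed * n_blk, 1L, rep(p_blk, each = n_seed)),
                  n_seed, n_blk)
    H[seq_len(n_seed), ] <- pat[, block_id, drop = FALSE]
    # boundaries where template switches may occur: rho within, always at chrom break
    rho_vec <- ifelse(rvec >= 0.5, 1, rho)
    for (k in seq.int(n_seed + 1L, length.out = n_hap - n_seed)) {
      cuts <- c(1L, which(stats::runif(L - 1L) < rho_vec) + 1L, L + 1L)
      seg_len <- diff(cuts)
      tmpl <- rep(sample.int(k - 1L, length(seg_len), replace = TRUE), seg_len)
      h <- H[cbind(tmpl, seq_len(L))]
      flips <- which(stats::runif(L) < mut)
      if (length(flips)) h[flips] <- 1L - h[flips]
      H[k, ] <- h
    }
    return(H)
  }
  stop("unknown init mode: ", mode)
}

#' Forward neutral Wright-Fisher simulation of a selfing demography
#'
#' Simulates the configured populations for `config$generations` discrete
#' generations with per-offspring selfing probability, crossover
#' recombination, infinite-sites-style mutation, split founding and
#' bottleneck resizes; migration is structurally absent. The same seed gives
#' bit-identical output.
#'
#' @param config a [demography_config()].
#' @param seed integer RNG seed.
#' @return list with elements `gm` (a [genotype_matrix()] of the sampled
#'   diploids) and `pop_map` (a [population_map()]; clade = population name,
#'   lineage from `config$lineages`).
#' @examples
#' cfg <- demography_config(data.frame(name = "p1", N = 50), generations = 5,
#'                          n_sites = 100, sample_sizes = c(p1 = 10))
#' sim <- simulate_neutral(cfg, seed = 1)
#' @export
simulate_neutral <- function(config, seed) {
  stopifnot(inherits(config, "demography_config"))
  set.seed(seed)
  map <- sim_site_map(config)
  pops <- config$populations
  roots <- setdiff(pops$name, if (is.null(config$splits)) character(0)
                              else config$splits$child)
  if (!length(roots)) stop("demography has no root population")

  live <- list()
  for (nm in roots) {
    N <- pops$N[pops$name == nm]
    live[[nm]] <- sim_init_haplotypes(N, config$n_sites, config$init, map$rvec)
  }

  size_at <- function(nm, g) {
    row <- pops[pops$name == nm, ]
    if (!is.null(row$bn_start) && !is.na(row$bn_start) &&
        g >= row$bn_start && g < row$bn_end) row$bn_size else row$N
  }

  for (g in seq_len(config$generations)) {
    if (!is.null(config$splits)) {
      due <- config$splits[config$splits$generation == g - 1L, , drop = FALSE]
      for (i in seq_len(nrow(due))) {
        par <- due$parent[i]; chl <- due$child[i]
        if (is.null(live[[par]])) stop("split parent '", par, "' not alive")
        Nc <- size_at(chl, g)
        n_par <- nrow(live[[par]]) %/% 2L
        founders <- if (Nc <= n_par) sample.int(n_par, Nc)
                    else sample.int(n_par, Nc, replace = TRUE)
        live[[chl]] <- live[[par]][as.vector(rbind(2L * founders - 1L,
                                                   2L * founders)), , drop = FALSE]
      }
    }
    for (nm in names(live)) {
      live[[nm]] <- sim_next_generation(live[[nm]], size_at(nm, g),
                                        config$selfing_rate, map$rvec,
                                        config$mutation_rate)
    }
  }

  ss <- config$sample_sizes
  dead <- setdiff(names(ss), names(live))
  if (length(dead))
    stop("sampled population(s) never founded by the end of the simulation: ",
         paste(dead, collapse = ", "),
         " (a split at generation g needs generations > g)")
  dos_blocks <- list(); ids <- character(0); clade <- character(0)
  for (nm in names(ss)) {
    hap <- live[[nm]]
    n_here <- nrow(hap) %/% 2L
    if (ss[[nm]] > n_here)
      stop("sample size for ", nm, " exceeds population size")
    pick <- sort(sample.int(n_here, ss[[nm]]))
    d <- hap[2L * pick - 1L, , drop = FALSE] + hap[2L * pick, , drop = FALSE]
    dos_blocks[[nm]] <- d
    ids <- c(ids, sprintf("%s_%03d", nm, seq_len(ss[[nm]])))
    clade <- c(clade, rep(nm, ss[[nm]]))
  }
  dos <- do.call(rbind, dos_blocks)
  gm <- genotype_matrix(dos, chrom = map$chrom, pos = map$pos, sample_ids = ids)
  lin <- config$lineages[clade]
  lin[is.na(lin)] <- clade[is.na(lin)]
  list(gm = gm, pop_map = population_map(ids, clade, unname(lin)))
}
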