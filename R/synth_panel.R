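#' Trait architecture for the synthetic vernalization panel
#'
#' Maps genotype at a set of causal sites additively onto the three free
#' parameters of the vernalization response: the minimum threshold duration
#' (MTD) of vernalization, the saturating duration, and the post-return days
#' to flower once saturated. Days to flower at sub-saturating durations are
#' generated from these via a fixed delay slope (extra days per missing week
#' of vernalization), so the "days after MTD" trait is implied rather than
#' independently parameterized.
#'
#' @param causal_sites data.frame with columns `site` (column index into the
#'   genotype matrix), `mtd_weeks`, `sat_weeks`, `dtf_days`: additive effect
#'   per alternate-allele dose on MTD, saturation and post-return days to
#'   flower. May have zero rows.
#' @param baseline numeric vector `c(mtd_weeks, sat_weeks, dtf_days)` for the
#'   dosage-zero genotype; defaults place the reference genotype inside the
#'   2-10 week treatment design (MTD 4 weeks, saturation 8 weeks, 40 days to
#'   spike emergence after return).
#' @param slope_days_per_week extra post-return days to flower per week of
#'   vernalization below saturation (default 7).
#' @param never_flower_mtd accessions whose genetic MTD exceeds this value
#'   never flower within the experiment (default `Inf`, i.e. rule disabled).
#' @return list of class `trait_architecture`.
#' @export
trait_architecture <- function(causal_sites = NULL,
                               baseline = c(mtd_weeks = 4, sat_weeks = 8,
                                            dtf_days = 40),
                               slope_days_per_week = 7,
                               never_flower_mtd = Inf) {
  if (is.null(causal_sites))
    causal_sites <- data.frame(site = integer(0), mtd_weeks = numeric(0),
                               sat_weeks = numeric(0), dtf_days = numeric(0))
  causal_sites <- as.data.frame(causal_sites)
  stopifnot(all(c("site", "mtd_weeks", "sat_weeks", "dtf_days") %in%
                  names(causal_sites)))
  structure(list(causal_sites = causal_sites, baseline = baseline,
                 slope_days_per_week = slope_days_per_week,
                 never_flower_mtd = never_flower_mtd),
            class = "trait_architecture")
}

#' Environment model: structure-correlated bioclimatic covariates
#'
#' Accession-level covariates are drawn from a multivariate normal whose mean
#' is the accession's clade mean: environment is correlated with population
#' structure exactly insofar as clade means differ. Emulates a bioclim-style
#' covariate set (e.g. 22 variables); it does not emulate raster extraction,
#' spatial autocorrelation within clades, or non-Gaussian variables.
#'
#' @param clade_means matrix (clades x variables) with rownames = clade
#'   labels and colnames = variable names.
#' @param within_sd per-variable within-clade standard deviation (scalar or
#'   vector of length `ncol(clade_means)`).
#' @param cor_mat cross-correlation matrix among variables (default
#'   identity); must be positive semi-definite.
#' @return list of class `env_model`.
#' @export
env_model <- function(clade_means, within_sd = 1, cor_mat = NULL) {
  clade_means <- as.matrix(clade_means)
  V <- ncol(clade_means)
  if (is.null(cor_mat)) cor_mat <- diag(V)
  if (!isSymmetric(unname(cor_mat)) || min(eigen(cor_mat, symmetric = TRUE,
                                                 only.values = TRUE)$values) < -1e-8)
    stop("cor_mat must be a symmetric positive semi-definite matrix")
  if (is.null(colnames(clade_means)))
    colnames(clade_means) <- paste0("env", seq_len(V))
  structure(list(clade_means = clade_means,
                 within_sd = rep_len(within_sd, V), cor_mat = cor_mat),
            class = "env_model")
}

#' Draw structure-correlated environmental covariates
#'
#' @param pop_map a [population_map()].
#' @param env an [env_model()] with `clade_means` rows covering every clade
#'   in `pop_map`.
#' @param seed integer RNG seed.
#' @return data.frame: `sample_id` plus one column per environmental variable.
#' @export
generate_environment <- function(pop_map, env, seed) {
  set.seed(seed)
  miss <- setdiff(unique(pop_map$clade), rownames(env$clade_means))
  if (length(miss)) stop("clade_means missing for clade(s): ",
                         paste(miss, collapse = ", "))
  V <- ncol(env$clade_means)
  n <- nrow(pop_map)
  Sigma <- diag(env$within_sd, V) %*% env$cor_mat %*% diag(env$within_sd, V)
  ev <- eigen(Sigma, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), V) %*% t(ev$vectors)
  z <- matrix(stats::rnorm(n * V), n, V) %*% rt
  x <- env$clade_means[pop_map$clade, , drop = FALSE] + z
  out <- data.frame(sample_id = pop_map$sample_id, x, check.names = FALSE)
  rownames(out) <- NULL
  out
}

# true trait values implied by genotypes under an architecture
true_traits_from_genotypes <- function(gm, arch) {
  cs <- arch$causal_sites
  if (nrow(cs) && (min(cs$site) < 1 || max(cs$site) > n_sites(gm)))
    stop("causal site index out of range")
  n <- n_accessions(gm)
  eff <- function(col) {
    if (!nrow(cs)) return(rep(0, n))
    d <- gm$dosages[, cs$site, drop = FALSE]
    d[d == -1L] <- 0L  # missing causal calls contribute nothing
    as.vector(d %*% cs[[col]])
  }
  mtd <- arch$baseline[[1]] + eff("mtd_weeks")
  sat <- pmax(mtd, arch$baseline[[2]] + eff("sat_weeks"))
  dtf <- arch$baseline[[3]] + eff("dtf_days")
  data.frame(
    sample_id = gm$sample_ids,
    mtd_weeks = mtd,
    days_after_mtd = dtf + arch$slope_days_per_week * (sat - mtd),
    saturation_weeks = sat,
    days_after_saturation = 7 * sat + dtf,
    never_flowered = mtd > arch$never_flower_mtd
  )
}

#' Generate replicated vernalization-response measurements
#'
#' Produces the long-format experiment table: for each accession, treatment
#' duration and replicate, the number of days from return to warm conditions
#' to spike emergence, or a censored record. Durations below the accession's
#' true MTD never flower; between MTD and saturation the post-return days
#' decrease linearly to the saturated value; at and beyond saturation they
#' are constant. Replicate noise is Gaussian and measurements land on the
#' 2-day scoring grid of the assay.
#'
#' @param true_traits data.frame as produced by the architecture: columns
#'   `sample_id`, `mtd_weeks`, `saturation_weeks`, `days_after_mtd`,
#'   `days_after_saturation`, optionally `never_flowered`.
#' @param design treatment durations in weeks (default `c(2, 4, 6, 8, 10)`,
#'   ascending) and `replicates` per cell (default 3).
#' @param replicates number of replicates per accession x duration cell.
#' @param noise_sd replicate noise standard deviation in days (default 2).
#' @param horizon_days experiment end: replicates exceeding this many days
#'   after return are censored (default 150).
#' @param seed integer RNG seed.
#' @return data.frame of class `vernalization_response`: columns `sample_id`,
#'   `duration_weeks`, `replicate`, `days_after_return` (NA when censored),
#'   `flowered`.
#' @export
generate_vernalization_response <- function(true_traits,
                                            design = c(2, 4, 6, 8, 10),
                                            replicates = 3L, noise_sd = 2,
                                            horizon_days = 150, seed = 1L) {
  stopifnot(noise_sd >= 0, !is.unsorted(design, strictly = TRUE))
  set.seed(seed)
  tt <- true_traits
  if (is.null(tt$never_flowered)) tt$never_flowered <- FALSE
  grid <- expand.grid(replicate = seq_len(replicates), duration_weeks = design,
                      row = seq_len(nrow(tt)))
  d <- grid$duration_weeks
  mtd <- tt$mtd_weeks[grid$row]
  sat <- tt$saturation_weeks[grid$row]
  d_sat <- tt$days_after_saturation[grid$row] - 7 * sat  # post-return days
  d_mtd <- tt$days_after_mtd[grid$row]
  frac <- ifelse(sat > mtd, pmin(pmax((sat - d) / (sat - mtd), 0), 1), 0)
  mu <- d_sat + (d_mtd - d_sat) * frac
  days <- 2 * round((mu + stats::rnorm(length(mu), 0, noise_sd)) / 2)
  days <- pmax(days, 0)
  flowered <- d >= mtd & days <= horizon_days & !tt$never_flowered[grid$row]
  out <- data.frame(sample_id = tt$sample_id[grid$row],
                    duration_weeks = d, replicate = grid$replicate,
                    days_after_return = ifelse(flowered, days, NA_real_),
                    flowered = flowered)
  out <- out[order(match(out$sample_id, tt$sample_id), out$duration_weeks,
                   out$replicate), ]
  rownames(out) <- NULL
  class(out) <- c("vernalization_response", "data.frame")
  attr(out, "design") <- design
  out
}

#' Simulate a full synthetic study panel
#'
#' Glues the neutral simulator, trait architecture, response-curve generator
#' and environment model into one object mirroring the study design: a
#' genotype panel with population structure, true flowering traits implied
#' by causal genotypes, a replicated vernalization experiment and a
#' structure-correlated covariate table, all sharing one population map.
#'
#' @param config a [demography_config()].
#' @param arch a [trait_architecture()].
#' @param env an [env_model()], or NULL to skip the covariate table.
#' @param design treatment durations in weeks, ascending.
#' @param replicates replicates per cell.
#' @param noise_sd replicate noise sd in days.
#' @param seed integer RNG seed (sub-seeds are derived for each component).
#' @return list of class `synthetic_study` with elements `gm`, `pop_map`,
#'   `true_traits`, `response`, `environment`.
#' @export
simulate_panel <- function(config, arch, env = NULL,
                           design = c(2, 4, 6, 8, 10), replicates = 3L,
                           noise_sd = 2, seed = 1L) {
  stopifnot(!is.unsorted(design, strictly = TRUE))
  sim <- simulate_neutral(config, seed = seed)
  tt <- true_traits_from_genotypes(sim$gm, arch)
  vr <- generate_vernalization_response(tt, design = design,
                                        replicates = replicates,
                                        noise_sd = noise_sd,
                                        seed = seed + 1000L)
  envtab <- if (is.null(env)) NULL else
    generate_environment(sim$pop_map, env, seed = seed + 2000L)
  structure(list(gm = sim$gm, pop_map = sim$pop_map, true_traits = tt,
                 response = vr, environment = envtab),
            class = "synthetic_study")
}
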