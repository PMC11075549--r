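# Covariance-aware differentiation: a moment-based (FLK-style) X^T^X
# statistic whitened by the scaled across-population allele-frequency
# covariance, calibrated on pseudo-observed datasets (PODs) drawn from the
# fitted neutral model.
#
# Because the per-site ancestral frequency is estimated as the allele-count
# weighted mean of the population frequencies, the standardized deviation
# vector alpha is confined, exactly, to the hyperplane orthogonal to the
# allele-count vector u = 2n. All second-moment estimation and whitening
# therefore happens in that (J-1)-dimensional deviation subspace, spanned by
# an orthonormal basis B of the complement of u: this keeps the whitening
# matrix well conditioned instead of inverting a covariance that is
# structurally singular along u.

# orthonormal basis of the complement of the allele-count vector
count_basis <- function(n) {
  J <- length(n)
  if (J < 2) stop("need >= 2 populations")
  qr.Q(qr(cbind(2 * n, diag(J))))[, 2:J, drop = FALSE]
}

# per-site weighted ancestral frequency and standardized deviations
freq_alpha <- function(freqs, n) {
  w <- 2 * n / sum(2 * n)
  pi_hat <- as.vector(freqs %*% w)
  keep <- pi_hat > 0 & pi_hat < 1
  list(pi = pi_hat, keep = keep,
       alpha = (freqs[keep, , drop = FALSE] - pi_hat[keep]) /
         sqrt(pi_hat[keep] * (1 - pi_hat[keep])))
}

# realized deviation-subspace second moments, with the expected binomial
# sampling variance subtracted (in alpha units) when correct_sampling
realized_moments <- function(freqs, n, B, correct_sampling = TRUE) {
  fa <- freq_alpha(freqs, n)
  beta <- fa$alpha %*% B
  M <- crossprod(beta) / nrow(beta)
  if (correct_sampling) {
    p <- freqs[fa$keep, , drop = FALSE]
    pi_ <- fa$pi[fa$keep]
    corr <- colMeans(p * (1 - p) / (pi_ * (1 - pi_))) *
      (2 * n / (2 * n - 1)) / (2 * n)
    M <- M - t(B) %*% (diag(corr, length(n)) %*% B)
  }
  M
}

clamp_pd <- function(M, floor_frac = 1e-3) {
  ev <- eigen(M, symmetric = TRUE)
  lam <- pmax(ev$values, max(ev$values) * floor_frac)
  ev$vectors %*% diag(lam, nrow(M)) %*% t(ev$vectors)
}

#' Construct a covariance model from known parameters
#'
#' For calibration experiments and tests where the scaled population
#' covariance `Omega`, the ancestral-frequency Beta parameters and the
#' sample sizes are specified rather than estimated.
#'
#' @param omega J x J symmetric positive semi-definite scaled covariance of
#'   population allele frequencies.
#' @param pi_params Beta parameters `c(a, b)` of the ancestral frequency.
#' @param n diploid sample sizes per population.
#' @return list of class `covariance_model`.
#' @export
covariance_model <- function(omega, pi_params, n) {
  omega <- as.matrix(omega)
  J <- ncol(omega)
  if (length(n) != J) stop("n must match omega dimension")
  if (!isSymmetric(unname(omega))) stop("omega must be symmetric")
  B <- count_basis(n)
  omega_beta <- t(B) %*% omega %*% B
  structure(list(omega = omega, omega_beta = omega_beta,
                 omega_beta_inv = solve(omega_beta), B = B,
                 pi_params = c(a = unname(pi_params[1]), b = unname(pi_params[2])),
                 n = n, n_sites_used = NA_integer_),
            class = "covariance_model")
}

#' Estimate the scaled population allele-frequency covariance
#'
#' Moment-based fit of the neutral model behind X^T^X: per site the
#' ancestral frequency is estimated as the allele-count-weighted mean of
#' population frequencies, deviations are standardized as
#' `alpha_j = (p_j - pi) / sqrt(pi (1 - pi))`, and the deviation-subspace
#' covariance is the site average of the outer products, with the expected
#' binomial sampling variance subtracted (`correct_sampling`; without it
#' small samples inflate the diagonal). Ancestral-frequency Beta parameters
#' are fit to the per-site `pi` by the method of moments.
#'
#' Because pseudo-observed data are generated from a *truncated* MVN (plus
#' binomial sampling), naive moments are not self-consistent: generating
#' from the raw estimate and re-estimating yields smaller values. With
#' `match_moments` (default TRUE) the generator covariance is therefore
#' iteratively adjusted until data simulated from the fitted model reproduce
#' the observed deviation moments, which is what makes the POD threshold
#' calibration a closed loop.
#'
#' @param freqs numeric matrix (sites x populations, J >= 2) of
#'   alternate-allele frequencies; sites with pooled frequency 0 or 1 are
#'   dropped.
#' @param n diploid sample sizes per population.
#' @param correct_sampling subtract the binomial sampling term (default
#'   TRUE).
#' @param match_moments calibrate the generator covariance through the
#'   truncation (default TRUE).
#' @param n_match loci per moment-matching iteration (default 4e4).
#' @param match_iter matching iterations (default 4).
#' @param seed RNG seed for the matching simulations.
#' @return list of class `covariance_model`: `omega` (generator covariance,
#'   lifted to J x J; zero along the count direction), `omega_beta` /
#'   `omega_beta_inv` (deviation-subspace scoring covariance), `B`,
#'   `pi_params`, `n`, `n_sites_used`.
#' @export
estimate_omega <- function(freqs, n, correct_sampling = TRUE,
                           match_moments = TRUE, n_match = 4e4,
                           match_iter = 4, seed = 1L) {
  freqs <- as.matrix(freqs)
  J <- ncol(freqs)
  if (length(n) != J) stop("n must give one diploid sample size per population")
  if (nrow(freqs) < 200) stop("need >= 200 sites to estimate the covariance")
  if (J == 1L) {
    # single population: no per-site ancestral estimate exists; standardize
    # against the across-sites mean frequency (total drift + spectrum spread)
    p <- freqs[freqs > 0 & freqs < 1, 1]
    pim <- mean(p)
    om <- matrix(mean((p - pim)^2 / (pim * (1 - pim))))
    m <- pim; v <- stats::var(p); k <- m * (1 - m) / v - 1
    return(structure(list(omega = om, omega_beta = om,
                          omega_beta_inv = solve(om), B = matrix(1, 1, 1),
                          pi_params = c(a = m * k, b = (1 - m) * k), n = n,
                          n_sites_used = length(p)),
                     class = "covariance_model"))
  }
  B <- count_basis(n)
  fa <- freq_alpha(freqs, n)
  target <- realized_moments(freqs, n, B, correct_sampling)
  pi_hat <- fa$pi[fa$keep]
  m <- mean(pi_hat); v <- stats::var(pi_hat)
  k <- m * (1 - m) / v - 1
  pi_params <- if (is.finite(k) && k > 0) c(a = m * k, b = (1 - m) * k)
               else {
    warning("degenerate ancestral-frequency moments; using Beta(1, 1)")
    c(a = 1, b = 1)
  }
  score_beta <- clamp_pd(target)
  gen_beta <- score_beta
  gen_pi <- pi_params
  if (match_moments) {
    set.seed(seed)
    beta_mom <- function(m, v) {
      v <- min(v, m * (1 - m) * 0.99)
      k <- m * (1 - m) / v - 1
      c(a = m * k, b = (1 - m) * k)
    }
    gen_m <- m; gen_v <- v
    for (it in seq_len(match_iter)) {
      proto <- structure(list(omega = B %*% gen_beta %*% t(B),
                              pi_params = gen_pi, n = n),
                         class = "covariance_model")
      sim <- draw_frequency_loci(proto, n_match,
                                 seed = sample.int(.Machine$integer.max, 1))
      R <- realized_moments(sim$p_sample, n, B, correct_sampling)
      gen_beta <- clamp_pd(gen_beta + (target - R))
      # also steer the generator's ancestral-frequency Beta so that the
      # *observed* per-site pi moments are reproduced through truncation
      # and binomial sampling
      sim_fa <- freq_alpha(sim$p_sample, n)
      sim_pi <- sim_fa$pi[sim_fa$keep]
      gen_m <- min(max(gen_m + (m - mean(sim_pi)), 0.02), 0.98)
      gen_v <- max(gen_v * (v / stats::var(sim_pi)), 1e-4)
      gen_pi <- beta_mom(gen_m, gen_v)
    }
  }
  structure(list(omega = B %*% gen_beta %*% t(B), omega_beta = score_beta,
                 omega_beta_inv = solve(score_beta), B = B,
                 pi_params = gen_pi, n = n, n_sites_used = nrow(fa$alpha)),
            class = "covariance_model")
}

#' The X^T^X covariance-aware differentiation statistic
#'
#' For each site, standardized population deviations
#' `alpha = (p - pi) / sqrt(pi (1 - pi))` (with `pi` the count-weighted mean
#' frequency) are whitened by the inverse of the model covariance restricted
#' to the deviation subspace: `XtX = alpha' B Omega_beta^-1 B' alpha`. Under
#' the neutral model the statistic is approximately chi-squared with J - 1
#' degrees of freedom (one degree is spent estimating `pi`); it is invariant
#' to allele polarity. Sites with `pi` of 0 or 1 are undefined (NA).
#'
#' @param freqs per-site population frequencies: numeric matrix
#'   (sites x populations) or a single vector of length J.
#' @param model a `covariance_model` from [estimate_omega()] or
#'   [covariance_model()].
#' @return numeric vector of X^T^X values (NA where undefined).
#' @export
xtx_statistic <- function(freqs, model) {
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1)
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != length(model$n))
    stop("freqs must have one column per population")
  fa <- freq_alpha(freqs, model$n)
  out <- rep(NA_real_, nrow(freqs))
  if (any(fa$keep)) {
    beta <- fa$alpha %*% model$B
    out[fa$keep] <- rowSums((beta %*% model$omega_beta_inv) * beta)
  }
  out
}

#' Draw loci from the fitted neutral frequency model
#'
#' The generating process behind the POD: ancestral frequency
#' `pi ~ Beta(a, b)`, population frequencies multivariate normal with mean
#' `pi` and covariance `pi (1 - pi) Omega`, truncated to `[0, 1]`, then
#' binomial allele counts at the observed sample sizes.
#'
#' @param model a `covariance_model`.
#' @param n_loci number of loci to draw.
#' @param seed integer RNG seed.
#' @return list with `p_true` (truncated MVN population frequencies) and
#'   `p_sample` (binomial-sampled frequency estimates), both `n_loci x J`.
#' @export
draw_frequency_loci <- function(model, n_loci, seed) {
  set.seed(seed)
  J <- ncol(model$omega)
  pi0 <- stats::rbeta(n_loci, model$pi_params[["a"]], model$pi_params[["b"]])
  ev <- eigen(model$omega, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), J) %*% t(ev$vectors)
  z <- matrix(stats::rnorm(n_loci * J), n_loci, J) %*% rt
  p <- pi0 + z * sqrt(pi0 * (1 - pi0))
  p <- pmin(pmax(p, 0), 1)
  counts <- matrix(stats::rbinom(n_loci * J, rep(2 * model$n, each = n_loci),
                                 as.vector(p)), n_loci, J)
  p_sample <- sweep(counts, 2, 2 * model$n, "/")
  list(p_true = p, p_sample = p_sample)
}

#' POD calibration of the X^T^X significance threshold
#'
#' Generates a pseudo-observed dataset of `n_loci` loci from the fitted
#' covariance model ([draw_frequency_loci()]), computes X^T^X on the sampled
#' frequencies exactly as for real data, and returns the requested quantile
#' of the defined values as the significance threshold (defaults: 100,000
#' loci, 0.99 quantile).
#'
#' @param model a `covariance_model`.
#' @param n_loci POD size (default 1e5).
#' @param quantile threshold quantile (default 0.99).
#' @param seed integer RNG seed; a fixed seed reproduces the threshold.
#' @return list with `threshold`, `quantile`, `n_loci`, `xtx` (the POD
#'   values).
#' @export
pod_calibrate <- function(model, n_loci = 1e5, quantile = 0.99, seed = 1L) {
  pod <- draw_frequency_loci(model, n_loci, seed)
  xtx <- xtx_statistic(pod$p_sample, model)
  thr <- stats::quantile(xtx, quantile, na.rm = TRUE, names = FALSE)
  list(threshold = thr, quantile = quantile, n_loci = n_loci, xtx = xtx)
}

#' Population allele frequencies from a genotype matrix
#'
#' Convenience bridge from genotypes to the frequency matrices consumed by
#' [estimate_omega()] and [xtx_statistic()].
#'
#' @param gm a [genotype_matrix()].
#' @param pop_map a [population_map()].
#' @param level `"clade"` (default) or `"lineage"`.
#' @return list with `freqs` (sites x populations) and `n` (median diploid
#'   sample size per population, for the binomial sampling model).
#' @export
population_frequencies <- function(gm, pop_map, level = c("clade", "lineage")) {
  level <- match.arg(level)
  mp <- match_population_map(gm, pop_map, level = level)
  groups <- levels(mp$group)
  freqs <- sapply(groups, function(g) {
    d <- gm$dosages[mp$idx[mp$group == g], , drop = FALSE]
    obs <- d != -1L
    colSums(d * obs) / (2 * colSums(obs))
  })
  n <- vapply(groups, function(g) {
    d <- gm$dosages[mp$idx[mp$group == g], , drop = FALSE]
    stats::median(colSums(d != -1L))
  }, numeric(1))
  list(freqs = freqs, n = n)
}
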