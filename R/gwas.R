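# Linear mixed-model association scan with centered kinship, BH-FDR and the
# windowed peak-calling rule (>= min_markers FDR-significant markers per
# 8 kb window, 4 kb step, qualifying windows merged).

#' Centered relatedness (kinship) matrix
#'
#' `K = Wc Wc' / p` where `Wc` is the site-wise mean-centered dosage matrix
#' over `p` sites; missing dosages are mean-imputed per site for this
#' computation only. Centering makes every row of `K` sum to zero;
#' monomorphic sites contribute zero.
#'
#' @param gm a [genotype_matrix()].
#' @return n x n symmetric matrix of class `matrix`, accessions in
#'   `gm$sample_ids` order.
#' @export
centered_kinship <- function(gm) {
  d <- gm$dosages
  d[d == -1L] <- NA
  mu <- colMeans(d, na.rm = TRUE)
  for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mu[j]
  Wc <- sweep(d, 2, mu)
  K <- tcrossprod(Wc) / ncol(d)
  dimnames(K) <- list(gm$sample_ids, gm$sample_ids)
  K
}

# REML log-likelihood machinery after rotation by the eigenvectors of K.
# Returns the per-SNP Wald fit given rotated covariates.
reml_wald <- function(yt, Xt, dvals, log_lambda_range = c(log(1e-5), log(1e5))) {
  n <- length(yt)
  c_ <- ncol(Xt)
  negloglik <- function(loglam) {
    w <- 1 / (exp(loglam) * dvals + 1)
    XtW <- Xt * w
    XX <- crossprod(Xt, XtW)
    Xy <- crossprod(XtW, yt)
    R <- tryCatch(chol(XX), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    beta <- backsolve(R, backsolve(R, Xy, transpose = TRUE))
    rss <- sum(w * (yt - Xt %*% beta)^2)
    # restricted likelihood up to constants
    0.5 * (-sum(log(w)) + 2 * sum(log(diag(R))) + (n - c_) * log(rss))
  }
  opt <- stats::optimize(negloglik, interval = log_lambda_range)
  lam <- exp(opt$minimum)
  w <- 1 / (lam * dvals + 1)
  XtW <- Xt * w
  XX <- crossprod(Xt, XtW)
  Xy <- crossprod(XtW, yt)
  XXi <- solve(XX)
  beta <- XXi %*% Xy
  rss <- sum(w * (yt - Xt %*% beta)^2)
  sigma2 <- rss / (n - c_)
  se <- sqrt(diag(XXi) * sigma2)
  list(beta = as.vector(beta), se = se, lambda = lam, df = n - c_)
}

#' Linear mixed-model association scan
#'
#' Per SNP fits `y = mu + x beta + u + e` with `u ~ N(0, sg^2 K)` and
#' `e ~ N(0, se^2 I)`: the kinship is eigendecomposed once, phenotype and
#' covariates are rotated, and the variance ratio `lambda = sg^2 / se^2` is
#' profiled per SNP by bounded scalar optimization of the restricted
#' likelihood on the log scale in `[1e-5, 1e5]`. The reported p-value is the
#' Wald test `beta / se(beta)` against a t distribution on `n - 2` degrees
#' of freedom, so with `K = I` the scan reproduces ordinary least-squares
#' regression. SNPs below `min_maf` are excluded; SNPs with missing calls
#' are fit on complete cases with the corresponding kinship submatrix.
#'
#' @param gm a [genotype_matrix()].
#' @param phenotype numeric vector, one value per accession in `gm` order
#'   (must be complete).
#' @param K kinship matrix from [centered_kinship()] (any symmetric PSD
#'   matrix in matching order).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return data.frame of class `lmm_fit`: `chrom`, `pos`, `maf`, `beta`,
#'   `se`, `wald`, `p`, `lambda`.
#' @export
lmm_assoc <- function(gm, phenotype, K, min_maf = 0.05) {
  n <- n_accessions(gm)
  if (length(phenotype) != n) stop("phenotype length must match accessions")
  if (anyNA(phenotype)) stop("phenotype must be complete")
  if (stats::sd(phenotype) == 0) stop("constant phenotype")
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-6 * max(abs(ev$values)))
    stop("kinship matrix is not positive semi-definite")
  dvals <- pmax(ev$values, 0)
  U <- ev$vectors
  yt <- crossprod(U, phenotype)
  ones_t <- crossprod(U, rep(1, n))

  gmf <- maf_filter(gm, min_maf)
  d <- gmf$dosages
  L <- ncol(d)
  f <- allele_freq(gmf)
  maf <- pmin(f, 1 - f)

  res <- matrix(NA_real_, L, 4,
                dimnames = list(NULL, c("beta", "se", "p", "lambda")))
  for (s in seq_len(L)) {
    x <- d[, s]
    if (any(x == -1L)) {
      ok <- x != -1L
      if (sum(ok) < 4 || stats::sd(x[ok]) == 0) next
      evs <- eigen(K[ok, ok], symmetric = TRUE)
      fit <- reml_wald(crossprod(evs$vectors, phenotype[ok]),
                       cbind(crossprod(evs$vectors, rep(1, sum(ok))),
                             crossprod(evs$vectors, x[ok])),
                       pmax(evs$values, 0))
    } else {
      if (stats::sd(x) == 0) next
      fit <- reml_wald(yt, cbind(ones_t, crossprod(U, x)), dvals)
    }
    res[s, ] <- c(fit$beta[2], fit$se[2],
                  2 * stats::pt(-abs(fit$beta[2] / fit$se[2]), df = fit$df),
                  fit$lambda)
  }
  out <- data.frame(chrom = gmf$chrom, pos = gmf$pos, maf = maf,
                    beta = res[, "beta"], se = res[, "se"],
                    wald = (res[, "beta"] / res[, "se"])^2,
                    p = res[, "p"], lambda = res[, "lambda"])
  out <- out[!is.na(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lmm_fit", "data.frame")
  out
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Sorts the p-values ascending; the largest `i` with
#' `p(i) <= i * alpha / m` defines the cutoff, and every p-value at or below
#' `p(i)` is rejected.
#'
#' @param pvals p-values in `(0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list: `rejected` (logical, input order), `threshold` (the cutoff
#'   p-value, or NA when nothing is rejected), `n_rejected`.
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  m <- length(pvals)
  if (!m) return(list(rejected = logical(0), threshold = NA_real_,
                      n_rejected = 0L))
  o <- order(pvals)
  ps <- pvals[o]
  ok <- ps <= seq_len(m) * alpha / m
  if (!any(ok))
    return(list(rejected = rep(FALSE, m), threshold = NA_real_,
                n_rejected = 0L))
  cut <- ps[max(which(ok))]
  rej <- pvals <= cut
  list(rejected = rej, threshold = cut, n_rejected = sum(rej))
}

#' Call associated regions by sliding-window marker counting
#'
#' Markers are first classified significant by [bh_fdr()] at `fdr_alpha`.
#' Half-open windows `[start, start + window_bp)` slide per chromosome at
#' `step_bp`; a window qualifies iff it contains at least `min_markers`
#' significant markers, and overlapping or adjacent qualifying windows are
#' merged into one region. Output is invariant to input marker order.
#'
#' @param fits an `lmm_fit` table (needs `chrom`, `pos`, `p`).
#' @param window_bp window span (default 8000).
#' @param step_bp window step (default 4000).
#' @param min_markers minimum significant markers per window (default 4).
#' @param fdr_alpha FDR level for marker significance (default 0.05).
#' @return data.frame of class `peak_regions`: `chrom`, `start`, `end`,
#'   `n_markers_above`, `min_p` (zero rows when nothing qualifies).
#' @export
call_peaks <- function(fits, window_bp = 8000L, step_bp = 4000L,
                       min_markers = 4L, fdr_alpha = 0.05) {
  sig <- bh_fdr(fits$p, fdr_alpha)$rejected
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_markers_above = integer(0),
                      min_p = numeric(0))
  class(empty) <- c("peak_regions", "data.frame")
  if (!any(sig)) return(empty)
  hits <- fits[sig, , drop = FALSE]
  regions <- list()
  for (ch in unique(hits$chrom)) {
    pos <- sort(hits$pos[hits$chrom == ch])
    starts <- seq.int(0L, max(pos), by = step_bp)
    qual <- vapply(starts, function(s)
      sum(pos >= s & pos < s + window_bp) >= min_markers, logical(1))
    if (!any(qual)) next
    qs <- starts[qual]
    qe <- qs + window_bp
    # merge overlapping/adjacent qualifying windows
    grp <- cumsum(c(TRUE, qs[-1] > utils::head(qe, -1)))
    for (g in unique(grp)) {
      s0 <- min(qs[grp == g]); e0 <- max(qe[grp == g])
      inside <- hits$chrom == ch & hits$pos >= s0 & hits$pos < e0
      regions[[length(regions) + 1L]] <-
        data.frame(chrom = ch, start = s0, end = e0,
                   n_markers_above = sum(inside),
                   min_p = min(hits$p[inside]))
    }
  }
  if (!length(regions)) return(empty)
  out <- do.call(rbind, regions)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_regions", "data.frame")
  out
}
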