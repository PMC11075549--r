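# Constrained ordination (RDA), Ezekiel-adjusted R2, permutation tests and
# the double-stopping forward selection used for trait ~ environment and
# trait ~ SNP models.

# expand a data.frame of numeric and factor variables to coding columns
# (one-hot with first level dropped), no intercept column
design_cols <- function(df) {
  df <- as.data.frame(df)
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Fit a redundancy analysis model
#'
#' Least-squares regression of a (centered) response matrix on a (centered)
#' design built from numeric and factor explanatory variables, followed by
#' ordination of the fitted values: the constrained axes are the principal
#' axes of the fitted-value matrix. With a single numeric response and
#' predictor this collapses to simple linear regression and `R2` equals the
#' squared Pearson correlation.
#'
#' @param Y response: numeric vector or matrix (n x q).
#' @param X explanatory variables: data.frame (factors allowed) or matrix.
#' @return object of class `rda_model`: list with `R2`, `R2adj`, `F_stat`,
#'   `coefficients`, `fitted`, `axes` (constrained axes scores), `rank`
#'   (columns actually fitted), `n`, plus the centered response and design.
#' @export
rda_fit <- function(Y, X) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  mm <- if (is.data.frame(X)) design_cols(X) else as.matrix(X)
  if (nrow(mm) != n) stop("Y and X row counts differ")
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(mm, scale = FALSE)
  qx <- qr(Xc)
  r <- qx$rank
  if (r < ncol(Xc)) {
    dropped <- colnames(Xc)[qx$pivot[-seq_len(r)]]
    warning("rank-deficient design; dropping aliased column(s): ",
            paste(dropped, collapse = ", "))
  }
  if (n <= r + 1) stop("need n > m + 1 (m = fitted design rank)")
  fit <- qr.fitted(qx, Yc)
  tot <- sum(Yc^2)
  R2 <- if (tot > 0) sum(fit^2) / tot else NA_real_
  R2adj <- adjusted_r2(R2, n, r)
  F_stat <- (R2 / r) / ((1 - R2) / (n - r - 1))
  sv <- svd(fit)
  k <- max(1L, sum(sv$d > max(sv$d[1], 0) * 1e-10))
  axes <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  structure(list(R2 = R2, R2adj = R2adj, F_stat = F_stat,
                 coefficients = qr.coef(qx, Yc), fitted = fit, axes = axes,
                 rank = r, n = n, Yc = Yc, Xc = Xc),
            class = "rda_model")
}

#' @export
print.rda_model <- function(x, ...) {
  cat(sprintf("rda_model: n = %d, m = %d, R2 = %.4f, R2adj = %.4f, F = %.3f\n",
              x$n, x$rank, x$R2, x$R2adj, x$F_stat))
  invisible(x)
}

#' Ezekiel-adjusted R-squared
#'
#' `R2adj = 1 - (1 - R2) * (n - 1) / (n - m - 1)`; may be negative.
#'
#' @param R2 unadjusted fraction of variance explained.
#' @param n number of observations.
#' @param m number of fitted explanatory columns (factor coding columns
#'   count individually).
#' @return the adjusted value.
#' @export
adjusted_r2 <- function(R2, n, m) {
  if (n <= m + 1) stop("adjusted R2 undefined for n <= m + 1")
  1 - (1 - R2) * (n - 1) / (n - m - 1)
}

# Machinery for the incremental F of Xadd on top of (intercept | Xcond).
# stat_cols(Ym): Ym holds one PERMUTED COPY of a single response per column
#   (univariate fast path) -> vector of F values.
# stat_mat(Ym): Ym is one n x q response -> scalar trace-based F.
incremental_f_machine <- function(n, Xadd, Xcond = NULL) {
  base <- cbind(rep(1, n), if (!is.null(Xcond)) as.matrix(Xcond))
  qc <- qr(base)
  Qc <- qr.Q(qc)[, seq_len(qc$rank), drop = FALSE]
  Xr <- as.matrix(Xadd) - Qc %*% crossprod(Qc, as.matrix(Xadd))
  qx <- qr(Xr)
  rx <- qx$rank
  Qx <- if (rx > 0) qr.Q(qx)[, seq_len(rx), drop = FALSE] else NULL
  df2 <- n - qc$rank - rx
  sums <- function(Ym) {
    ssx <- colSums(crossprod(Qx, Ym)^2)
    ssc <- colSums(crossprod(Qc, Ym)^2)
    list(ssx = ssx, rss = colSums(Ym^2) - ssc - ssx)
  }
  list(
    rank_add = rx, df2 = df2, Qc = Qc,
    stat_cols = function(Ym) {
      s <- sums(Ym)
      (s$ssx / rx) / (s$rss / df2)
    },
    stat_mat = function(Ym) {
      s <- sums(Ym)
      (sum(s$ssx) / rx) / (sum(s$rss) / df2)
    }
  )
}

# permutation F test for Xadd | (intercept, Xcond). Free permutation of Y
# rows when Xcond is NULL; residual permutation under the reduced model
# otherwise. Multivariate responses use the trace-based F.
perm_f_test <- function(Y, Xadd, Xcond = NULL, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  mach <- incremental_f_machine(n, Xadd, Xcond)
  if (mach$rank_add == 0 || mach$df2 <= 0)
    return(list(F_obs = NA_real_, p = NA_real_, n_perm = n_perm))
  F_obs <- mach$stat_mat(Y)
  if (is.null(Xcond)) {
    base <- Y
  } else {
    fit_c <- mach$Qc %*% crossprod(mach$Qc, Y)
    resid_c <- Y - fit_c
  }
  if (ncol(Y) == 1L) {
    perms <- replicate(n_perm, sample.int(n))
    Yp <- if (is.null(Xcond)) matrix(Y[perms], n, n_perm)
          else matrix(resid_c[perms], n, n_perm) + as.vector(fit_c)
    F_perm <- mach$stat_cols(Yp)
  } else {
    F_perm <- vapply(seq_len(n_perm), function(i) {
      pr <- sample.int(n)
      Yp <- if (is.null(Xcond)) Y[pr, , drop = FALSE]
            else resid_c[pr, , drop = FALSE] + fit_c
      mach$stat_mat(Yp)
    }, numeric(1))
  }
  p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
  list(F_obs = F_obs, p = p, n_perm = n_perm)
}

#' Permutation test of an RDA model
#'
#' Permutes rows of the response (or, when conditioning variables are
#' supplied, of the residuals under the reduced model), recomputes the F
#' statistic, and reports the add-one p-value
#' `(1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`. A fixed seed reproduces the
#' p-value exactly.
#'
#' @param model an `rda_model` from [rda_fit()], or a raw response
#'   vector/matrix (then `X` is required).
#' @param X explanatory design (only when `model` is a raw response).
#' @param Xcond optional conditioning design: the test becomes a partial test
#'   of `X` given `Xcond` under residual permutation.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer RNG seed; NULL (default) continues the ambient RNG
#'   stream.
#' @return list with `F_obs`, `p`, `n_perm`.
#' @export
rda_permutation_test <- function(model, X = NULL, Xcond = NULL,
                                 n_perm = 999, seed = NULL) {
  stopifnot(n_perm >= 99)
  if (inherits(model, "rda_model")) {
    Y <- model$Yc
    Xadd <- model$Xc
  } else {
    Y <- as.matrix(model)
    if (is.null(X)) stop("X required when model is a raw response")
    Xadd <- if (is.data.frame(X)) design_cols(X) else as.matrix(X)
  }
  if (!is.null(Xcond) && is.data.frame(Xcond)) Xcond <- design_cols(Xcond)
  perm_f_test(Y, Xadd, Xcond, n_perm = n_perm, seed = seed)
}

#' Double-stopping forward selection of RDA predictors
#'
#' Replicates the `ordiR2step`-style procedure: starting from the
#' intercept-only empty model, at each step the candidate variable (a factor
#' counts as one candidate and its coding columns enter as a block) whose
#' addition maximizes the cumulative Ezekiel-adjusted R2 is identified, its
#' addition is tested by permutation (free permutation from the empty model,
#' residual permutation under the reduced model afterwards), and it is
#' admitted only if its addition improves the cumulative adjusted R2, its
#' p-value is at most `Pin` and — when `R2scope` — the new cumulative
#' adjusted R2 does not exceed the adjusted R2 of the full model containing
#' all candidates. Selection stops at the first inadmissible best candidate.
#'
#' @param Y response vector (or single-column matrix).
#' @param candidates data.frame of candidate variables (numeric or factor
#'   columns).
#' @param Pin admission p-value threshold (default 0.01).
#' @param n_perm permutations per admission test (default 1000).
#' @param R2scope cap cumulative adjusted R2 at the full-model value
#'   (default TRUE).
#' @param seed integer RNG seed.
#' @return list of class `selection_trace`: `trace` (data.frame with columns
#'   `variable`, `cum_R2adj`, `AIC`, `F`, `p`), `scope_R2adj` (full-model
#'   adjusted R2), `selected`, `stopped_because`.
#' @export
forward_select <- function(Y, candidates, Pin = 0.01, n_perm = 1000,
                           R2scope = TRUE, seed = 1L) {
  set.seed(seed)
  Y <- as.matrix(Y)
  if (ncol(Y) != 1L) stop("forward_select expects a single response variable")
  candidates <- as.data.frame(candidates)
  if (!ncol(candidates)) stop("no candidate variables supplied")
  n <- nrow(Y)
  Yc <- scale(Y, scale = FALSE)

  model_fit <- function(vars) {
    mm <- design_cols(candidates[, vars, drop = FALSE])
    qx <- qr(scale(mm, scale = FALSE))
    r <- qx$rank
    fit <- qr.fitted(qx, Yc)
    R2 <- sum(fit^2) / sum(Yc^2)
    list(R2 = R2, R2adj = adjusted_r2(R2, n, r), rank = r,
         rss = sum((Yc - fit)^2))
  }

  scope_R2adj <- if (R2scope) model_fit(names(candidates))$R2adj else Inf

  selected <- character(0)
  remaining <- names(candidates)
  trace <- data.frame(variable = character(0), cum_R2adj = numeric(0),
                      AIC = numeric(0), F = numeric(0), p = numeric(0))
  stopped <- "no admissible candidate"
  eps <- sqrt(.Machine$double.eps)
  cur_adj <- 0  # adjusted R2 of the intercept-only empty model

  while (length(remaining)) {
    cand_adj <- vapply(remaining,
                       function(v) model_fit(c(selected, v))$R2adj, numeric(1))
    best <- remaining[which.max(cand_adj)]
    best_adj <- max(cand_adj)
    if (best_adj <= cur_adj) {
      stopped <- "no adjusted-R2 improvement"
      break
    }
    if (R2scope && best_adj > scope_R2adj + eps) {
      stopped <- "R2scope exceeded"
      break
    }
    Xcond <- if (length(selected))
      design_cols(candidates[, selected, drop = FALSE]) else NULL
    Xadd <- design_cols(candidates[, best, drop = FALSE])
    tst <- perm_f_test(Yc, Xadd, Xcond, n_perm = n_perm)
    if (is.na(tst$p) || tst$p > Pin) {
      stopped <- "p > Pin"
      break
    }
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    fit <- model_fit(selected)
    cur_adj <- fit$R2adj
    aic <- n * log(fit$rss / n) + 2 * (fit$rank + 1)
    trace <- rbind(trace, data.frame(variable = best, cum_R2adj = fit$R2adj,
                                     AIC = aic, F = tst$F_obs, p = tst$p))
    if (!length(remaining)) stopped <- "all candidates admitted"
  }
  structure(list(trace = trace, scope_R2adj = scope_R2adj,
                 selected = selected, stopped_because = stopped),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("forward selection trace (scope R2adj =",
      formatC(x$scope_R2adj, digits = 4, format = "f"), "):\n")
  print(x$trace, row.names = FALSE)
  cat("stopped:", x$stopped_because, "\n")
  invisible(x)
}

#' Principal component analysis of a covariate table
#'
#' Columns are centered and scaled before the decomposition (i.e. PCA of the
#' correlation matrix); constant columns are dropped with a warning.
#'
#' @param X numeric matrix or data.frame of covariates.
#' @return list with `scores`, `loadings`, `var_fraction` (sums to 1).
#' @export
pca_covariates <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need n >= 2")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  list(scores = pr$x, loadings = pr$rotation,
       var_fraction = pr$sdev^2 / sum(pr$sdev^2))
}

#' Kendall rank correlation (tau-b) with normal-approximation p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3); ties allowed, but a
#'   fully tied vector is an error.
#' @return list with `tau` and `p` (two-sided).
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("kendall tau undefined for an all-tied vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value)
}
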