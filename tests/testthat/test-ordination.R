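test_that("rda_fit matches an independent normal-equations oracle and vegan", {
  set.seed(11)
  n <- 45
  X <- data.frame(a = rnorm(n), b = rnorm(n),
                  cl = factor(sample(c("u", "v", "w"), n, TRUE)))
  y <- 1.5 * X$a - 2 * (X$cl == "v") + rnorm(n)
  m <- rda_fit(y, X)
  # normal-equations oracle
  mm <- cbind(1, model.matrix(~ . , X)[, -1])
  beta <- solve(t(mm) %*% mm, t(mm) %*% y)
  fitted <- mm %*% beta
  R2_oracle <- sum((fitted - mean(y))^2) / sum((y - mean(y))^2)
  expect_equal(m$R2, R2_oracle, tolerance = 1e-10)
  skip_if_not_installed("vegan")
  vm <- vegan::rda(y ~ a + b + cl, data = X)
  ra <- vegan::RsquareAdj(vm)
  expect_equal(m$R2, ra$r.squared, tolerance = 1e-10)
  expect_equal(m$R2adj, ra$adj.r.squared, tolerance = 1e-10)
})

test_that("rda_fit handles the degenerate contracts", {
  set.seed(2)
  x <- rnorm(20)
  y <- 3 * x + rnorm(20)
  m <- rda_fit(y, data.frame(x = x))
  expect_equal(m$R2, cor(x, y)^2, tolerance = 1e-12)
  # orthogonal response: R2 exactly 0
  m0 <- rda_fit(residuals(lm(y ~ x)), data.frame(x = x))
  expect_lt(m0$R2, 1e-20)
  # aliased column dropped with warning
  expect_warning(ma <- rda_fit(y, data.frame(x = x, x2 = 2 * x)), "aliased")
  expect_equal(ma$rank, 1L)
  expect_error(rda_fit(y[1:3], data.frame(x = x[1:3], z = rnorm(3))),
               "n > m")
})

test_that("adjusted_r2 follows the Ezekiel formula", {
  expect_equal(adjusted_r2(0.37, 50, 0), 0.37)
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_equal(adjusted_r2(0.1, 10, 5), 1 - 0.9 * 9 / 4)  # negative is fine
  expect_error(adjusted_r2(0.5, 7, 6), "undefined")
})

test_that("permutation p-values behave at the extremes and reproduce", {
  set.seed(3)
  x <- rnorm(30)
  m <- rda_fit(x, data.frame(x = x))  # perfect fit
  t1 <- rda_permutation_test(m, n_perm = 199, seed = 5)
  expect_equal(t1$p, 1 / 200)
  t2 <- rda_permutation_test(m, n_perm = 199, seed = 5)
  expect_identical(t1$p, t2$p)
  expect_error(rda_permutation_test(m, n_perm = 10), "99")
})

test_that("null permutation p-values are roughly uniform", {
  set.seed(4)
  n <- 25
  ps <- replicate(200, {
    y <- rnorm(n); x <- rnorm(n)
    rda_permutation_test(rda_fit(y, data.frame(x = x)), n_perm = 99)$p
  })
  expect_equal(length(unique(ps)) > 20, TRUE)
  expect_lt(abs(mean(ps) - 0.5), 0.07)
  # super-uniformity under the null: P(p <= t) must not exceed t by more
  # than binomial noise (add-one p-values are discrete, so plain KS against
  # the continuous uniform is inappropriate)
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / length(ps)))
  }
})

test_that("forward_select admits a perfect predictor and stops on noise", {
  set.seed(6)
  y <- rnorm(40)
  tr <- forward_select(y, data.frame(self = y), Pin = 0.01, n_perm = 199)
  expect_equal(tr$selected, "self")
  expect_equal(nrow(tr$trace), 1L)
  expect_equal(tr$trace$cum_R2adj, 1)
  # pure noise: nothing admitted at a strict Pin, trace may be empty
  cand <- as.data.frame(matrix(rnorm(40 * 5), 40))
  tr0 <- forward_select(rnorm(40), cand, Pin = 0.001, n_perm = 199, seed = 8)
  expect_lte(nrow(tr0$trace), 1L)
})

test_that("forward_select agrees with vegan ordiR2step on a clear signal", {
  skip_if_not_installed("vegan")
  suppressMessages(library(vegan))  # ordiR2step's update() needs vegan attached
  set.seed(7)
  n <- 60
  cand <- data.frame(g1 = rnorm(n), g2 = rnorm(n), n1 = rnorm(n))
  y <- cand$g1 * 1.2 + cand$g2 * 0.8 + rnorm(n, 0, 0.8)
  tr <- forward_select(y, cand, Pin = 0.05, n_perm = 499, seed = 9)
  m0 <- vegan::rda(y ~ 1, data = cand)
  m1 <- vegan::rda(y ~ ., data = cand)
  vs <- vegan::ordiR2step(m0, m1, Pin = 0.05, R2scope = TRUE, trace = FALSE,
                          permutations = 499)
  vegan_vars <- setdiff(all.vars(formula(vs)), c("y", "."))
  expect_equal(tr$selected, vegan_vars)
  expect_equal(tr$selected[1], "g1")
  # cumulative R2adj of the first admitted variable matches vegan's value
  expect_equal(tr$trace$cum_R2adj[1],
               vegan::RsquareAdj(vegan::rda(y ~ g1, data = cand))$adj.r.squared,
               tolerance = 1e-10)
})

test_that("a lone strong predictor among pure noise trips the scope cap as in vegan", {
  # with one true predictor and only-noise alternatives, the full-model
  # adjusted R2 can fall below the single-variable one; ordiR2step then
  # refuses the step, and so do we (power analyses use R2scope = FALSE)
  set.seed(7)
  n <- 60
  cand <- data.frame(good = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  y <- cand$good * 1.2 + rnorm(n, 0, 0.8)
  tr <- forward_select(y, cand, Pin = 0.05, n_perm = 199, seed = 9)
  expect_equal(nrow(tr$trace), 0L)
  expect_equal(tr$stopped_because, "R2scope exceeded")
  tr2 <- forward_select(y, cand, Pin = 0.05, n_perm = 199, R2scope = FALSE,
                        seed = 9)
  expect_equal(tr2$selected[1], "good")
})

test_that("forward_select honors the R2scope cap and factor blocks", {
  set.seed(10)
  n <- 50
  cl <- factor(sample(c("p", "q", "r"), n, TRUE))
  x <- rnorm(n)
  y <- 2 * (cl == "q") + x + rnorm(n)
  cand <- data.frame(cl = cl, x = x, noise = rnorm(n))
  tr <- forward_select(y, cand, Pin = 0.05, n_perm = 199, seed = 11)
  expect_true("cl" %in% tr$selected)  # factor admitted as one block
  expect_true(all(tr$trace$cum_R2adj <= tr$scope_R2adj + 1e-8))
  expect_true(all(tr$trace$p <= 0.05))
  # trace R2adj is non-decreasing
  expect_true(all(diff(tr$trace$cum_R2adj) >= 0))
})

test_that("pca_covariates normalizes variance fractions", {
  set.seed(12)
  x <- rnorm(100)
  X <- cbind(a = x, b = x * 2 + 1e-8 * rnorm(100), c = rnorm(100),
             d = rnorm(100))
  p <- pca_covariates(X)
  expect_equal(sum(p$var_fraction), 1)
  expect_gt(p$var_fraction[1], 0.45)  # two collinear vars dominate PC1
  p2 <- pca_covariates(cbind(X[, 1:2]))
  expect_gt(p2$var_fraction[1], 0.999)
  expect_warning(pca_covariates(cbind(X, k = rep(1, 100))), "constant")
  # isotropic noise: each of 4 PCs near 25%
  Xi <- matrix(rnorm(4000), 1000, 4)
  expect_true(all(abs(pca_covariates(Xi)$var_fraction - 0.25) < 0.05))
})

test_that("kendall_tau matches the O(n^2) oracle including ties", {
  expect_equal(kendall_tau(1:8, (1:8)^2)$tau, 1)
  expect_equal(kendall_tau(1:8, rev(1:8))$tau, -1)
  x <- c(1, 2, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6, 5)
  expect_equal(kendall_tau(x, y)$tau, kendall_oracle(x, y), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:5) {
    a <- sample(1:5, 12, TRUE); b <- sample(1:5, 12, TRUE)
    if (length(unique(a)) == 1 || length(unique(b)) == 1) next
    expect_equal(kendall_tau(a, b)$tau, kendall_oracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "all-tied")
  expect_error(kendall_tau(1:2, 2:1), "n >= 3")
})
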