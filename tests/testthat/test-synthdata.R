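test_that("simulate_neutral is reproducible and respects config errors", {
  cfg <- demography_config(data.frame(name = "p1", N = 40), generations = 5,
                           n_sites = 60, sample_sizes = c(p1 = 10),
                           init = list(mode = "uniform", lo = 0.2, hi = 0.8))
  a <- simulate_neutral(cfg, seed = 9)
  b <- simulate_neutral(cfg, seed = 9)
  expect_identical(a$gm$dosages, b$gm$dosages)
  expect_identical(as.data.frame(a$pop_map), as.data.frame(b$pop_map))
  c2 <- simulate_neutral(cfg, seed = 10)
  expect_false(identical(a$gm$dosages, c2$gm$dosages))
  expect_error(demography_config(data.frame(name = "p1", N = 1)), ">= 2")
  expect_error(
    demography_config(data.frame(name = "p1", N = 10),
                      splits = data.frame(parent = "p1", child = "nope",
                                          generation = 1)),
    "declared")
})

test_that("complete selfing drives heterozygosity to near zero", {
  cfg <- demography_config(data.frame(name = "p1", N = 80),
                           generations = 200, selfing_rate = 1,
                           n_sites = 400, recomb = 0.5,
                           sample_sizes = c(p1 = 60),
                           init = list(mode = "uniform", lo = 0.3, hi = 0.7))
  sim <- simulate_neutral(cfg, seed = 4)
  expect_lt(heterozygosity_fraction(sim$gm), 0.01)
})

test_that("zero divergence time gives near-zero mean F_ST", {
  cfg <- demography_config(
    data.frame(name = c("p1", "p2"), N = 150),
    splits = data.frame(parent = "p1", child = "p2", generation = 0),
    selfing_rate = 0, generations = 1, n_sites = 600, recomb = 0.5,
    sample_sizes = c(p1 = 100, p2 = 100),
    init = list(mode = "uniform", lo = 0.2, hi = 0.8))
  sim <- simulate_neutral(cfg, seed = 5)
  fst <- weir_cockerham_fst(sim$gm, sim$pop_map, level = "clade")
  expect_lt(abs(mean(fst$theta, na.rm = TRUE)), 0.01)
})

test_that("selfing shifts genotypes toward 2pq(1-F) heterozygosity", {
  for (s in c(0, 0.5, 0.99)) {
    cfg <- demography_config(data.frame(name = "p1", N = 150),
                             generations = 25, selfing_rate = s,
                             n_sites = 800, recomb = 0.5,
                             sample_sizes = c(p1 = 150),
                             init = list(mode = "uniform", lo = 0.3, hi = 0.7))
    sim <- simulate_neutral(cfg, seed = 60 + round(100 * s))
    d <- sim$gm$dosages
    p <- colMeans(d) / 2
    seg <- p > 0.05 & p < 0.95
    obs_het <- mean(colMeans(d[, seg] == 1L))
    Fis <- s / (2 - s)
    exp_het <- mean(2 * p[seg] * (1 - p[seg])) * (1 - Fis)
    expect_lt(abs(obs_het - exp_het), 0.05)
  }
})

test_that("mutation-driven site-frequency spectrum is decreasing", {
  cfg <- demography_config(data.frame(name = "p1", N = 60),
                           generations = 250, selfing_rate = 0,
                           mutation_rate = 4e-4, n_sites = 4000, recomb = 0.5,
                           sample_sizes = c(p1 = 60),
                           init = list(mode = "monomorphic"))
  sim <- simulate_neutral(cfg, seed = 8)
  p <- colMeans(sim$gm$dosages) / 2
  p <- p[p > 0 & p < 1]
  expect_gt(length(p), 300)
  counts <- hist(p, breaks = seq(0, 1, 0.2), plot = FALSE)$counts
  # binned derived-allele spectrum: rare >> intermediate >> common
  expect_true(counts[1] > counts[2] && counts[2] >= counts[3])
})

test_that("bottlenecks and splits change sampled diversity as configured", {
  base <- demography_config(
    data.frame(name = c("anc", "p2"), N = c(100, 100)),
    splits = data.frame(parent = "anc", child = "p2", generation = 0),
    selfing_rate = 0.9, generations = 40, n_sites = 500,
    sample_sizes = c(anc = 30, p2 = 30),
    init = list(mode = "uniform", lo = 0.2, hi = 0.8))
  bn <- base
  bn$populations <- data.frame(name = c("anc", "p2"), N = c(100, 100),
                               bn_start = c(NA, 5), bn_end = c(NA, 35),
                               bn_size = c(NA, 5))
  sim_b <- simulate_neutral(bn, seed = 12)
  sim_0 <- simulate_neutral(base, seed = 12)
  seg <- function(gm, ids) {
    p <- colMeans(gm$dosages[ids, ]) / 2
    mean(p > 0 & p < 1)
  }
  i2 <- grep("^p2", sim_b$gm$sample_ids)
  # the bottlenecked daughter keeps fewer segregating sites
  expect_lt(seg(sim_b$gm, i2), seg(sim_0$gm, i2) - 0.05)
})

test_that("true traits follow the architecture additively", {
  gm <- genotype_matrix(rbind(c(0L, 0L), c(2L, 0L), c(0L, 1L)),
                        c("c1", "c1"), c(1L, 2L))
  arch <- grid_architecture()
  tt <- true_traits_from_genotypes(gm, arch)
  expect_equal(tt$mtd_weeks, c(2, 6, 2))
  expect_equal(tt$saturation_weeks, c(6, 10, 6))
  expect_equal(tt$days_after_saturation, 7 * c(6, 10, 6) + c(30, 30, 36))
  expect_equal(tt$days_after_mtd, c(30, 30, 36) + 7 * c(4, 4, 4))
  # zero-effect architecture: everyone at baseline
  arch0 <- trait_architecture()
  tt0 <- true_traits_from_genotypes(gm, arch0)
  expect_true(all(tt0$mtd_weeks == 4) && all(tt0$days_after_saturation == 96))
  bad <- trait_architecture(data.frame(site = 99L, mtd_weeks = 1,
                                       sat_weeks = 1, dtf_days = 1))
  expect_error(true_traits_from_genotypes(gm, bad), "out of range")
})

test_that("vernalization response censors below MTD and is exact at sd 0", {
  tt <- data.frame(sample_id = "x", mtd_weeks = 6, days_after_mtd = 60,
                   saturation_weeks = 8, days_after_saturation = 7 * 8 + 46)
  vr <- generate_vernalization_response(tt, noise_sd = 0, seed = 2)
  expect_false(any(vr$flowered[vr$duration_weeks < 6]))
  expect_equal(unique(vr$days_after_return[vr$duration_weeks == 6]), 60)
  expect_equal(unique(vr$days_after_return[vr$duration_weeks >= 8]), 46)
  # noise_sd 0: replicates identical within duration
  expect_true(all(tapply(vr$days_after_return[vr$flowered],
                         vr$duration_weeks[vr$flowered],
                         function(v) length(unique(v)) == 1)))
  # measurements land on the 2-day grid even with noise
  vr2 <- generate_vernalization_response(tt, noise_sd = 3, seed = 3)
  expect_true(all(vr2$days_after_return[vr2$flowered] %% 2 == 0))
})

test_that("generate_environment reproduces clade means and correlations", {
  pm <- population_map(sprintf("a%03d", 1:300),
                       rep(c("X", "Y", "Z"), each = 100))
  mu <- rbind(X = c(0, 0), Y = c(5, -5), Z = c(-5, 5))
  colnames(mu) <- c("bio1", "bio12")
  # zero within-clade sd: every accession equals its clade mean
  e0 <- env_model(mu, within_sd = 1e-12)
  tab0 <- generate_environment(pm, e0, seed = 1)
  expect_equal(unname(as.matrix(tab0[c(1, 101, 201), -1])), unname(mu),
               tolerance = 1e-6)
  # stated cross-correlation 0.9 recovered within 0.1 at n = 300
  e1 <- env_model(mu * 0, within_sd = 1,
                  cor_mat = matrix(c(1, 0.9, 0.9, 1), 2))
  tab1 <- generate_environment(pm, e1, seed = 2)
  expect_lt(abs(cor(tab1$bio1, tab1$bio12) - 0.9), 0.1)
  # identical clade means: between-clade variance ~ 0 relative to total
  av <- tapply(tab1$bio1, pm$clade, mean)
  expect_lt(var(av) / var(tab1$bio1), 0.05)
  expect_error(env_model(mu, cor_mat = matrix(c(1, 2, 2, 1), 2)),
               "semi-definite")
  expect_error(generate_environment(
    population_map("q", "W"), e0, seed = 1), "clade_means")
})

test_that("simulate_panel glues components under one population map", {
  cfg <- clade_config(n_sites = 200L, generations = 12L,
                      sample_per_clade = 6L)
  arch <- grid_architecture()
  mu <- matrix(rnorm(10), 5, 2,
               dimnames = list(c("A_East", "A_Italia", "B_East", "B_West", "C"),
                               c("bio1", "bio2")))
  panel <- simulate_panel(cfg, arch, env_model(mu), noise_sd = 0, seed = 21)
  expect_setequal(panel$pop_map$sample_id, panel$gm$sample_ids)
  expect_setequal(unique(panel$response$sample_id), panel$gm$sample_ids)
  expect_setequal(panel$environment$sample_id, panel$gm$sample_ids)
  expect_equal(nrow(panel$response), 30 * 5 * 3)
  # reproducibility end to end
  panel2 <- simulate_panel(cfg, arch, env_model(mu), noise_sd = 0, seed = 21)
  expect_identical(panel$true_traits, panel2$true_traits)
  expect_identical(panel$response, panel2$response)
})
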