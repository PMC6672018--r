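test_that("generators are deterministic given the seed and require one", {
  s1 <- sim_pair_genotypes(n_loci = 20, seed = 1)
  s2 <- sim_pair_genotypes(n_loci = 20, seed = 1)
  expect_identical(s1, s2)
  expect_false(identical(s1$geno, sim_pair_genotypes(n_loci = 20, seed = 2)$geno))
  expect_error(sim_pair_genotypes(n_loci = 5), "seed")
  expect_error(sim_species_table(10), "seed")
  expect_error(sim_bottleneck_windows(50), "seed")
  expect_error(sim_tree_traits(10), "seed")
  t1 <- sim_tree_traits(10, seed = 3)
  t2 <- sim_tree_traits(10, seed = 3)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
})

test_that("pair simulator hits its analytic diversity targets", {
  sim <- sim_pair_genotypes(n_loci = 1500, locus_length = 300, seed = 5)
  est <- pi_b(count_site_classes(sim$geno, sim$classes))
  pi4 <- est$pi_b[est$class == "4D"]
  pi0 <- est$pi_b[est$class == "0D"]
  # per-locus pi has CV ~ 1 (exponential coalescence time), so allow 3 SE
  se <- sim$truth$pi_4d * 1.2 / sqrt(1500)
  expect_lt(abs(pi4 - sim$truth$pi_4d), 3 * se)
  expect_equal(pi0 / pi4, sim$truth$sel_reduction, tolerance = 0.15)
})

test_that("closed-form pair coalescent mean matches simulation under epochs", {
  ep <- tibble::tibble(size = c(3e5, 3e6), start = c(0, 4e5))
  prof <- sim_bottleneck_windows(8000, seed = 17, epochs = ep)
  expect_equal(attr(prof, "mean_s"), attr(prof, "truth")$mean_s,
    tolerance = 0.05
  )
  expect_error(
    sim_bottleneck_windows(
      10,
      seed = 1,
      epochs = tibble::tibble(size = 1e6, start = 5)
    ),
    "start"
  )
})

test_that("bottleneck severity orders the dispersion of S", {
  base <- tibble::tibble(size = 1e6, start = 0)
  mild <- tibble::tibble(size = c(5e5, 2e6), start = c(0, 3e5))
  extreme <- tibble::tibble(size = c(1e12, 0), start = c(0, 1e6))
  d <- function(ep) {
    p <- sim_bottleneck_windows(3000, seed = 23, epochs = ep)
    attr(p, "var_s") / constant_size_null(attr(p, "mean_s"))
  }
  # Poisson limit sits far below the geometric null; bottleneck above constant
  expect_lt(d(extreme), 0.5)
  expect_gt(d(mild), d(base))
  p <- sim_bottleneck_windows(3000, seed = 23, epochs = extreme)
  expect_equal(attr(p, "dispersion"), 1, tolerance = 0.1)
})

test_that("species-table generator embeds the sweep-model truth", {
  st <- sim_species_table(n_species = 38, nuT = 0.1, sigma = 0, seed = 2)
  pred <- expected_pi(
    N0 = st$truth$N0, mu = st$truth$mu, J = st$truth$J,
    nuT = 0.1, nc = st$data$nc
  )
  expect_equal(st$data$pi_4d, pred)
  # nuT = 0: no nc association beyond noise (residual after removing N0)
  st0 <- sim_species_table(n_species = 200, nuT = 0, sigma = 0.2, seed = 3)
  r <- pearson_cor(
    dplyr::mutate(st0$data, res = pi_4d / (4 * st0$truth$N0 * st0$truth$mu)),
    "res", "nc"
  )
  expect_lt(abs(r$r), 0.15)
  expect_error(
    sim_species_table(10, body_coef = c(1e5, -1e5), seed = 1),
    "non-positive N0"
  )
})

test_that("tree-trait generator respects the signal parameter", {
  t0 <- sim_tree_traits(60, lambda = 0, seed = 5)
  # independent traits: phylogenetic covariance of trait is ~0
  fit0 <- pagel_lambda(t0$tree, t0$trait)
  expect_lte(fit0$lambda_hat, 0.3)
  t1 <- sim_tree_traits(60, lambda = 1, seed = 6)
  fit1 <- pagel_lambda(t1$tree, t1$trait)
  expect_gte(fit1$lambda_hat, 0.7)
})

test_that("saturation simulation approaches the 0.75 ceiling from below", {
  low <- sim_saturation_divergence(2e4, subs_per_site = 0.05, seed = 1)
  high <- sim_saturation_divergence(2e4, subs_per_site = 20, seed = 1)
  expect_lt(low, 0.2)
  expect_equal(high, 0.75, tolerance = 0.02)
})
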