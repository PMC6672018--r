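test_that("background-selection factor matches its closed form and bounds", {
  expect_equal(bgs_factor(1, 13), exp(-4 / 13))
  expect_equal(bgs_factor(1, 31), exp(-4 / 31))
  expect_equal(bgs_factor(0, 20), 1)
  expect_error(bgs_factor(1, 0), "positive")
  expect_error(bgs_factor(-1, 10), "non-negative")
  # increasing in nc, decreasing in UT, in (0, 1]
  nc <- 13:31
  b <- bgs_factor(1, nc)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0 & b <= 1))
  expect_true(all(bgs_factor(2, nc) < b))
})

test_that("sweep kernel evaluates and is monotone in s on its domain", {
  expect_equal(sweep_J(1e-4, 1e6), 1e-4 / (2 * log(2 * 1e6 * 1e-4)))
  s <- 10^seq(-5, -0.5, length.out = 40)
  j <- sweep_J(s, 1e6)
  expect_true(all(diff(j) > 0))
  expect_warning(expect_true(is.na(sweep_J(1e-7, 1e6))), "weak selection")
})

test_that("expected diversity reduces correctly at the model's limits", {
  # no selection: E[pi] = pi0 exactly
  expect_equal(expected_pi(N0 = 1e6, mu = 2.9e-9, nuT = 0, nc = 25, UT = 0),
    4 * 1e6 * 2.9e-9,
    tolerance = 1e-12
  )
  # direct evaluation of the sweep-only form
  expect_equal(
    expected_pi(pi0 = 0.02, mu = 2.9e-9, J = 1e-5, nuT = 0.133, nc = 25),
    0.02 / (8 * (0.02 / (4 * 2.9e-9)) * 1e-5 * 0.133 / 25 + 1)
  )
  # E[pi] <= pi0, equality iff no selection; increasing in nc under selection
  nc <- 13:31
  e <- expected_pi(N0 = 2e6, nuT = 0.1, nc = nc)
  expect_true(all(e < 4 * 2e6 * 2.9e-9))
  expect_true(all(diff(e) > 0))
  eU <- expected_pi(N0 = 2e6, nuT = 0, nc = nc, UT = 1)
  expect_true(all(eU < 4 * 2e6 * 2.9e-9))
  # inconsistent pi0 / N0 pairs are rejected
  expect_error(
    expected_pi(N0 = 1e6, pi0 = 0.5, nc = 25),
    "inconsistent"
  )
})

test_that("log-slope limit is 1/nc and bounds the numeric derivative", {
  expect_equal(log_slope_limit(25), 0.04)
  expect_equal(log_slope_limit(13), 1 / 13)
  dln <- function(nuT, nc, h = 1e-3) {
    (log(expected_pi(N0 = 2e6, nuT = nuT, nc = nc + h)) -
      log(expected_pi(N0 = 2e6, nuT = nuT, nc = nc - h))) / (2 * h)
  }
  # high-sweep-rate limit attains 1/nc
  expect_equal(dln(1e6, 25), 0.04, tolerance = 1e-4)
  # bound holds across moderate rates
  for (nuT in c(0, 0.01, 0.1, 1, 10)) {
    for (nc in c(13, 25, 31)) {
      expect_lte(dln(nuT, nc), 1 / nc + 1e-8)
    }
  }
})

test_that("sweep-rate fit recovers noiseless truth and the zero boundary", {
  st <- sim_species_table(n_species = 38, nuT = 0.1, sigma = 0, seed = 11)
  fit <- fit_sweep_rate(st$data, seed = 2)
  expect_lt(abs(fit$nuT_hat - 0.1) / 0.1, 0.01)
  expect_lt(fit$ssq, 1e-10)
  # predictions reproduce observations without noise
  expect_equal(fit$predictions$pi_pred, fit$predictions$pi_obs,
    tolerance = 1e-4
  )
  st0 <- sim_species_table(n_species = 38, nuT = 0, sigma = 0, seed = 12)
  fit0 <- fit_sweep_rate(st0$data, seed = 2)
  expect_lt(fit0$nuT_hat, 1e-3)
})

test_that("fitted model compresses the diversity range relative to data", {
  st <- sim_species_table(n_species = 38, nuT = 0.133, sigma = 0.4, seed = 21)
  fit <- fit_sweep_rate(st$data, seed = 3)
  rng <- predicted_range(fit)
  expect_lt(rng$pred_ratio, rng$obs_ratio)
  expect_gt(rng$pred_min, 0)
  # noiseless fit: predicted range equals observed range
  st0 <- sim_species_table(n_species = 38, nuT = 0.133, sigma = 0, seed = 22)
  rng0 <- predicted_range(fit_sweep_rate(st0$data, seed = 3))
  expect_equal(rng0$pred_ratio, rng0$obs_ratio, tolerance = 1e-2)
})

test_that("sweep fit validates inputs and exposes tidy methods", {
  st <- sim_species_table(n_species = 10, sigma = 0.1, seed = 31)
  expect_error(fit_sweep_rate(st$data[1:2, ]), "at least 3")
  bad <- st$data
  bad$body_size[1] <- -5
  expect_error(fit_sweep_rate(bad), "positive")
  fit <- fit_sweep_rate(st$data, seed = 1, n_starts = 5)
  expect_equal(tidy(fit)$term, c("nuT", "N0_intercept", "N0_slope"))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(nrow(fit$starts), 5)
})
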