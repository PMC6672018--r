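test_that("lambda transform leaves the diagonal and lambda = 1 is identity", {
  tt <- sim_tree_traits(10, seed = 1)
  C <- ape::vcv(tt$tree)
  expect_equal(lambda_transform(C, 1), C)
  V0 <- lambda_transform(C, 0)
  expect_equal(diag(V0), diag(C))
  expect_true(all(V0[upper.tri(V0)] == 0))
})

test_that("lambda likelihood at the optimum dominates a 101-point grid", {
  tt <- sim_tree_traits(30, lambda = 0.6, seed = 2)
  fit <- pagel_lambda(tt$tree, tt$trait)
  C <- ape::vcv(tt$tree)
  grid <- seq(0, 1, length.out = 101)
  lls <- vapply(
    grid,
    function(l) lepdiv:::bm_profile_lnl(C, tt$trait[rownames(C)], l)$lnl,
    numeric(1)
  )
  expect_gte(fit$lnl_hat, max(lls) - 1e-6)
  expect_gte(fit$lnl_hat, max(fit$lnl_zero, fit$lnl_one) - 1e-6)
})

test_that("lambda ML matches an independent implementation", {
  skip_if_not_installed("phytools")
  tt <- sim_tree_traits(40, lambda = 0.7, seed = 3)
  fit <- pagel_lambda(tt$tree, tt$trait)
  ref <- phytools::phylosig(tt$tree, tt$trait, method = "lambda", test = TRUE)
  expect_equal(fit$lambda_hat, ref$lambda, tolerance = 1e-3)
  expect_equal(fit$lnl_hat, ref$logL, tolerance = 1e-4)
})

test_that("lambda recovery separates Brownian from independent traits", {
  bm <- vapply(1:10, function(s) {
    tt <- sim_tree_traits(50, lambda = 1, seed = 500 + s)
    pagel_lambda(tt$tree, tt$trait)$lambda_hat
  }, numeric(1))
  iid <- vapply(1:10, function(s) {
    tt <- sim_tree_traits(50, lambda = 0, seed = 600 + s)
    pagel_lambda(tt$tree, tt$trait)$lambda_hat
  }, numeric(1))
  expect_gte(median(bm), 0.8)
  expect_lte(median(iid), 0.1)
})

test_that("degenerate inputs are flagged, not guessed", {
  tt <- sim_tree_traits(10, seed = 4)
  expect_error(
    pagel_lambda(tt$tree, rep(1, 10)),
    "zero variance"
  )
  star <- ape::stree(10, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  x <- stats::setNames(rnorm(10), star$tip.label)
  expect_warning(fs <- pagel_lambda(star, x), "flat")
  expect_true(is.na(fs$lambda_hat))
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  d <- tibble::tibble(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  got <- anova_oneway(d, "y", "g")
  # SSB = 3*(2-3.5)^2 + 3*(5-3.5)^2 = 13.5; MSW = 4/4 = 1
  expect_equal(got$statistic, 13.5)
  expect_equal(c(got$df1, got$df2), c(1, 4))
  # F = 0 when all group means are equal
  d0 <- tibble::tibble(y = rep(c(1, 2), 3), g = rep(c("a", "b", "c"), each = 2))
  expect_equal(anova_oneway(d0, "y", "g")$statistic, 0)
  # location shift and scale invariance
  d2 <- dplyr::mutate(d, y = 10 + 3 * y)
  expect_equal(anova_oneway(d2, "y", "g")$statistic, 13.5)
  expect_error(anova_oneway(dplyr::mutate(d, g = "a"), "y", "g"), "2 groups")
})

test_that("pearson_cor reproduces exact and sampled correlations", {
  d <- tibble::tibble(x = 1:10, y = 1:10)
  expect_equal(pearson_cor(d, "x", "y")$r, 1)
  expect_equal(pearson_cor(dplyr::mutate(d, y = -y + 5), "x", "y")$r, -1)
  expect_error(pearson_cor(dplyr::mutate(d, y = 1), "x", "y"), "zero variance")
  # sampling distribution at rho = 0.5, n = 38
  set.seed(8)
  rs <- replicate(100, {
    x <- rnorm(38)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(38)
    pearson_cor(tibble::tibble(x = x, y = y), "x", "y")$r
  })
  expect_gte(mean(rs > 0.2 & rs < 0.75), 0.95)
  d38 <- tibble::tibble(x = rnorm(38), y = rnorm(38))
  expect_equal(pearson_cor(d38, "x", "y")$df, 36)
})

test_that("bonferroni helper adjusts a screen of p-values", {
  p <- c(0.01, 0.04, 0.2)
  expect_equal(adjust_bonferroni(p), pmin(1, p * 3))
})
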