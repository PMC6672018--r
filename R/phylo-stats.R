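#' Phylogenetic signal by Pagel's lambda
#'
#' Maximum-likelihood estimate of Pagel's lambda for a continuous trait on
#' a rooted tree. The trait is modelled as multivariate Gaussian with
#' covariance proportional to the Brownian-motion matrix of shared branch
#' lengths whose off-diagonal entries are multiplied by lambda in [0, 1];
#' lambda = 0 means tip values are independent of the phylogeny, lambda = 1
#' is plain Brownian motion. The mean and rate are profiled analytically
#' at each lambda and the 1-D likelihood is maximized by bounded search
#' (tolerance 1e-6). The reported p-value is a likelihood-ratio test of
#' lambda = 0 against chi-squared(1); the estimate lies on the boundary
#' under the null, making this convention conservative, and a zero LRT
#' yields p = 1.
#'
#' @param tree `phylo` object, rooted, with branch lengths; tips must match
#'   `names(trait)` (or the trait is taken in tip order when unnamed).
#' @param trait Numeric per-tip trait values (>= 4 tips, finite, non-zero
#'   variance).
#'
#' @return Object of class `lambda_fit`: list with `lambda_hat`,
#'   `lnl_hat`, `lnl_zero`, `lnl_one`, `p_value`, `sig2`, `mu`, `n`.
#'   Methods: `tidy()`, `glance()`. On a star phylogeny (no shared
#'   branches) the likelihood is flat in lambda; `lambda_hat` is `NA` and
#'   a warning is raised.
#' @export
pagel_lambda <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 4) stop("need at least 4 tips", call. = FALSE)
  if (!is.null(names(trait))) {
    stopifnot(setequal(names(trait), tree$tip.label))
    trait <- trait[tree$tip.label]
  }
  stopifnot(length(trait) == n, all(is.finite(trait)))
  if (stats::var(trait) == 0) {
    stop("trait has zero variance; lambda is undefined", call. = FALSE)
  }
  C <- ape::vcv(tree)
  offdiag <- C[upper.tri(C)]
  lnl <- function(lambda) bm_profile_lnl(C, trait, lambda)
  if (all(offdiag == 0)) {
    warning("star phylogeny: likelihood is flat in lambda; returning NA",
      call. = FALSE
    )
    l0 <- lnl(0)
    return(structure(
      list(
        lambda_hat = NA_real_, lnl_hat = l0$lnl, lnl_zero = l0$lnl,
        lnl_one = l0$lnl, p_value = 1, sig2 = l0$sig2, mu = l0$mu, n = n,
        flat = TRUE
      ),
      class = "lambda_fit"
    ))
  }
  opt <- stats::optimize(function(l) lnl(l)$lnl,
    interval = c(0, 1),
    maximum = TRUE, tol = 1e-6
  )
  cand <- list(
    list(lambda = 0, fit = lnl(0)),
    list(lambda = 1, fit = lnl(1)),
    list(lambda = opt$maximum, fit = lnl(opt$maximum))
  )
  best <- cand[[which.max(vapply(cand, function(x) x$fit$lnl, numeric(1)))]]
  lrt <- 2 * (best$fit$lnl - cand[[1]]$fit$lnl)
  p <- if (lrt <= 0) 1 else stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(
    list(
      lambda_hat = best$lambda,
      lnl_hat = best$fit$lnl,
      lnl_zero = cand[[1]]$fit$lnl,
      lnl_one = cand[[2]]$fit$lnl,
      p_value = p,
      sig2 = best$fit$sig2, mu = best$fit$mu, n = n,
      flat = FALSE
    ),
    class = "lambda_fit"
  )
}

# profile log-likelihood of the lambda-scaled BM model:
# mean and rate maximized analytically via GLS
bm_profile_lnl <- function(C, x, lambda) {
  V <- lambda_transform(C, lambda)
  n <- length(x)
  ch <- chol(V)
  logdet <- 2 * sum(log(diag(ch)))
  one <- rep(1, n)
  Vi_x <- backsolve(ch, forwardsolve(t(ch), x))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), one))
  mu <- sum(one * Vi_x) / sum(one * Vi_1)
  r <- x - mu
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  sig2 <- sum(r * Vi_r) / n
  lnl <- -0.5 * (n * log(2 * pi * sig2) + logdet + n)
  list(lnl = lnl, mu = mu, sig2 = sig2)
}

#' Lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal entries by `lambda`, leaving the diagonal
#' (tip-specific total variance) unchanged; `lambda = 1` returns the
#' matrix itself.
#'
#' @param C Phylogenetic covariance matrix (e.g. `ape::vcv(tree)`).
#' @param lambda Scalar in \[0, 1\].
#' @return Transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  V <- lambda * C
  diag(V) <- diag(C)
  V
}

#' @exportS3Method base::print
print.lambda_fit <- function(x, ...) {
  cat(sprintf(
    "Pagel's lambda = %s (n = %d tips), LRT p vs lambda = 0: %.3g\n",
    format(x$lambda_hat, digits = 4), x$n, x$p_value
  ))
  invisible(x)
}

#' @export
tidy.lambda_fit <- function(x, ...) {
  tibble::tibble(
    term = c("lambda", "mu", "sig2"),
    estimate = c(x$lambda_hat, x$mu, x$sig2)
  )
}

#' @export
glance.lambda_fit <- function(x, ...) {
  tibble::tibble(
    lambda_hat = x$lambda_hat, lnl_hat = x$lnl_hat,
    lnl_zero = x$lnl_zero, lnl_one = x$lnl_one,
    p_value = x$p_value, n = x$n
  )
}

#' One-way ANOVA of a trait across groups
#'
#' Classical fixed-effects F test, e.g. neutral diversity across taxonomic
#' families. Thin tidy wrapper around [stats::aov()].
#'
#' @param data Tibble.
#' @param value,group Column names (strings) of the response and grouping
#'   variable.
#' @return One-row tibble `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(data, value, group) {
  stopifnot(value %in% names(data), group %in% names(data))
  dd <- data.frame(y = data[[value]], g = factor(data[[group]]))
  if (nlevels(dd$g) < 2) stop("need at least 2 groups", call. = FALSE)
  tab <- summary(stats::aov(y ~ g, data = dd))[[1]]
  tibble::tibble(
    statistic = tab[["F value"]][1],
    df1 = tab[["Df"]][1],
    df2 = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1]
  )
}

#' Pearson correlation with test
#'
#' Thin tidy wrapper around [stats::cor.test()], e.g. for mitochondrial vs
#' nuclear diversity.
#'
#' @param data Tibble.
#' @param x,y Column names (strings).
#' @return One-row tibble `r`, `df`, `p_value`.
#' @export
pearson_cor <- function(data, x, y) {
  xv <- data[[x]]
  yv <- data[[y]]
  stopifnot(length(xv) == length(yv), length(xv) >= 3)
  if (stats::var(xv) == 0 || stats::var(yv) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(xv, yv, method = "pearson")
  tibble::tibble(
    r = unname(ct$estimate),
    df = unname(ct$parameter),
    p_value = ct$p.value
  )
}

#' Bonferroni adjustment helper
#'
#' @param p Vector of p-values from a multi-predictor screen.
#' @return Bonferroni-adjusted p-values ([stats::p.adjust()]).
#' @export
adjust_bonferroni <- function(p) {
  stats::p.adjust(p, method = "bonferroni")
}
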