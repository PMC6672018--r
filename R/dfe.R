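#' Gamma-DFE shape from the cross-species diversity ratio
#'
#' Under the nearly neutral theory with gamma-distributed deleterious
#' effects, the ratio of non-synonymous to synonymous diversity scales with
#' effective population size so that regressing `ln(pi_0D/pi_4D)` on
#' `ln(pi_4D)` across species gives a line whose negative slope equals the
#' gamma shape parameter beta. The fit is ordinary least squares by
#' default; an optional phylogenetic GLS mode uses a Brownian covariance
#' derived from a tree. The 95% confidence interval comes from a seeded
#' nonparametric bootstrap over species (percentile interval).
#'
#' @param data Tibble with one row per species and columns `species`,
#'   `pi_4d`, `pi_0d` (strictly positive).
#' @param bootstrap_reps Bootstrap replicates for the CI (default 1000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param tree Optional `phylo` object; when supplied with
#'   `method = "gls"`, the line is fitted by generalized least squares with
#'   Brownian correlation among species (tips must match `data$species`).
#' @param method `"ols"` (default) or `"gls"`.
#'
#' @return An object of class `dfe_fit`: a list with `beta` (= minus the
#'   fitted slope), `ci_low`, `ci_high`, `intercept`, `n`, and a `points`
#'   tibble carrying `ln_pi4`, `ln_ratio`, fitted values and residuals.
#'   Methods: [tidy()][generics::tidy], [glance()][generics::glance],
#'   [autoplot()][ggplot2::autoplot].
#' @export
beta_slope <- function(data, bootstrap_reps = 1000, seed = 1,
                       tree = NULL, method = c("ols", "gls")) {
  method <- match.arg(method)
  stopifnot(all(c("species", "pi_4d", "pi_0d") %in% names(data)))
  if (nrow(data) < 3) {
    stop("need at least 3 species to fit the diversity-ratio slope",
      call. = FALSE
    )
  }
  bad <- data$pi_4d <= 0 | data$pi_0d <= 0 |
    !is.finite(data$pi_4d) | !is.finite(data$pi_0d)
  if (any(bad)) {
    stop("non-positive diversity for species: ",
      paste(data$species[bad], collapse = ", "),
      call. = FALSE
    )
  }
  pts <- tibble::tibble(
    species = data$species,
    ln_pi4 = log(data$pi_4d),
    ln_ratio = log(data$pi_0d / data$pi_4d)
  )
  if (method == "gls") {
    if (is.null(tree)) stop("method = 'gls' needs a tree", call. = FALSE)
    if (!requireNamespace("nlme", quietly = TRUE)) {
      stop("method = 'gls' needs the nlme package", call. = FALSE)
    }
    dd <- as.data.frame(pts)
    rownames(dd) <- dd$species
    fit <- nlme::gls(ln_ratio ~ ln_pi4,
      data = dd,
      correlation = ape::corBrownian(phy = tree, form = ~species)
    )
    coefs <- stats::coef(fit)
  } else {
    fit <- stats::lm(ln_ratio ~ ln_pi4, data = pts)
    coefs <- stats::coef(fit)
  }
  pts$fitted <- coefs[1] + coefs[2] * pts$ln_pi4
  pts$residual <- pts$ln_ratio - pts$fitted

  boot <- boot_slopes(pts$ln_pi4, pts$ln_ratio, bootstrap_reps, seed)
  ci <- stats::quantile(-boot, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  structure(
    list(
      beta = unname(-coefs[2]),
      intercept = unname(coefs[1]),
      ci_low = ci[1], ci_high = ci[2],
      n = nrow(pts),
      bootstrap_reps = bootstrap_reps,
      method = method,
      points = pts
    ),
    class = "dfe_fit"
  )
}

# vectorized OLS slope bootstrap over species resamples
boot_slopes <- function(x, y, reps, seed) {
  n <- length(x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vapply(seq_len(reps), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    xi <- x[idx]
    yi <- y[idx]
    vx <- stats::var(xi)
    if (vx == 0) {
      return(NA_real_)
    }
    stats::cov(xi, yi) / vx
  }, numeric(1))
}

# helpers to leave the caller's RNG stream untouched
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Species deviations from the fitted diversity-ratio line
#'
#' Residuals of the beta fit ordered from most positive (selection less
#' efficient than predicted for that neutral diversity, e.g. recently
#' bottlenecked or structured species) to most negative.
#'
#' @param fit A [beta_slope()] fit.
#' @return Tibble `species`, `residual`, sorted decreasing.
#' @export
residual_rank <- function(fit) {
  stopifnot(inherits(fit, "dfe_fit"))
  dplyr::arrange(
    dplyr::select(fit$points, "species", "residual"),
    dplyr::desc(.data$residual)
  )
}

#' @exportS3Method base::print
print.dfe_fit <- function(x, ...) {
  cat(sprintf(
    "Gamma-DFE shape from diversity-ratio scaling (%s, n = %d)\n",
    toupper(x$method), x$n
  ))
  cat(sprintf(
    "  beta = %.3f  (95%% bootstrap CI %.3f-%.3f, %d reps)\n",
    x$beta, x$ci_low, x$ci_high, x$bootstrap_reps
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.dfe_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "beta"),
    estimate = c(x$intercept, x$beta),
    conf.low = c(NA_real_, x$ci_low),
    conf.high = c(NA_real_, x$ci_high)
  )
}

#' @importFrom generics glance
#' @export
glance.dfe_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, ci_low = x$ci_low, ci_high = x$ci_high,
    n = x$n, method = x$method
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.dfe_fit <- function(object, ...) {
  ggplot2::ggplot(
    object$points,
    ggplot2::aes(x = .data$ln_pi4, y = .data$ln_ratio)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = -object$beta,
      linetype = 2
    ) +
    ggplot2::labs(
      x = expression(ln(pi["4D"])),
      y = expression(ln(pi["0D"] / pi["4D"])),
      title = sprintf("DFE shape beta = %.2f", object$beta)
    ) +
    ggplot2::theme_minimal()
}
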