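#' Analytic model of neutral diversity under linked selection
#'
#' Expected neutral diversity given background selection (BGS) and
#' recurrent selective sweeps acting homogeneously along the genome:
#' \deqn{E[\pi] = \frac{\pi_0}{2 N_0 J \nu / r_c + B^{-1}}}
#' with \eqn{\pi_0 = 4 N_0 \mu} the diversity absent selection. Scaling
#' deleterious-mutation and sweep rates per genome and proxying total map
#' length by the haploid chromosome number \eqn{n_c} (about 50 cM per
#' chromosome in the recombining sex and achiasmate female meiosis) gives
#' \eqn{\nu/r \approx 4\nu_T/n_c} and \eqn{B \approx \exp(-4 U_T/n_c)}, so
#' \deqn{E[\pi] = \frac{\pi_0}{8 N_0 J \nu_T n_c^{-1} + e^{4 U_T/n_c}}.}
#' With \eqn{U_T = 0} this is the sweep-only form
#' \eqn{E[\pi]/\pi_0 = (8 N_0 J \nu_T n_c^{-1} + 1)^{-1}}.
#'
#' @name linked_selection
#' @keywords internal
NULL

#' Background-selection factor B
#'
#' Proportional reduction of linked neutral diversity due to purifying
#' selection, `B = exp(-4 * UT / nc)`.
#'
#' @param UT Genome-wide deleterious mutation rate per generation (>= 0).
#' @param nc Haploid chromosome number (> 0), the map-length proxy.
#' @return B in (0, 1], vectorized.
#' @examples
#' bgs_factor(1, 13) # ~0.735
#' @export
bgs_factor <- function(UT, nc) {
  if (any(nc <= 0)) stop("nc must be positive", call. = FALSE)
  if (any(UT < 0)) stop("UT must be non-negative", call. = FALSE)
  exp(-4 * UT / nc)
}

#' Sweep coalescence kernel J
#'
#' Probability kernel for a sweep causing coalescence at a linked neutral
#' site, `J = s / (2 * log(2 * Ne * s))` for a semi-dominant beneficial
#' allele with homozygous selection coefficient `s`. Only valid for
#' strongly selected sweeps, `2 * Ne * s > 1`.
#'
#' @param s Homozygous selection coefficient (> 0).
#' @param Ne Effective population size.
#' @return J, vectorized; `NA` with a warning outside the domain.
#' @examples
#' sweep_J(1e-4, 1e6) # ~9.4e-6
#' @export
sweep_J <- function(s, Ne) {
  if (any(s <= 0)) stop("s must be positive", call. = FALSE)
  weak <- 2 * Ne * s <= 1
  if (any(weak)) {
    warning("sweep_J undefined for 2*Ne*s <= 1 (weak selection); NA returned",
      call. = FALSE
    )
  }
  ifelse(weak, NA_real_, s / (2 * log(2 * Ne * s)))
}

#' Expected diversity under sweeps and background selection
#'
#' Evaluates the chromosome-number-scaled model (see
#' [linked_selection]). Supply either `N0` (with `mu`) or `pi0`
#' directly; when both are given they must satisfy `pi0 = 4 * N0 * mu`.
#'
#' @param N0 Baseline population size.
#' @param mu Per-site per-generation mutation rate.
#' @param J Sweep coalescence kernel value (see [sweep_J()]).
#' @param nuT Genome-wide sweep rate per generation (>= 0).
#' @param nc Haploid chromosome number (> 0).
#' @param UT Genome-wide deleterious mutation rate (default 0: sweep-only).
#' @param pi0 Diversity absent selection; default `4 * N0 * mu`.
#' @return Expected pairwise neutral diversity, vectorized.
#' @examples
#' expected_pi(N0 = 0.02 / (4 * 2.9e-9), mu = 2.9e-9, J = 1e-5, nuT = 0.133, nc = 25)
#' @export
expected_pi <- function(N0, mu = 2.9e-9, J = 1e-5, nuT = 0, nc, UT = 0,
                        pi0 = 4 * N0 * mu) {
  if (any(nc <= 0)) stop("nc must be positive", call. = FALSE)
  if (any(nuT < 0) || any(UT < 0)) {
    stop("rates nuT and UT must be non-negative", call. = FALSE)
  }
  if (missing(N0)) N0 <- pi0 / (4 * mu)
  if (any(abs(pi0 - 4 * N0 * mu) > 1e-12 * pmax(pi0, 1e-300))) {
    stop("inconsistent parameterization: pi0 must equal 4*N0*mu",
      call. = FALSE
    )
  }
  pi0 / (8 * N0 * J * nuT / nc + exp(4 * UT / nc))
}

#' Maximum sensitivity of log diversity to chromosome number
#'
#' In the limit of a high sweep rate the derivative of `ln(E[pi])` with
#' respect to `nc` tends to `1/nc`, the steepest slope the sweep model can
#' produce for the diversity-vs-chromosome-number relationship.
#'
#' @param nc Haploid chromosome number (> 0).
#' @return `1 / nc`, vectorized.
#' @examples
#' log_slope_limit(25) # 0.04
#' @export
log_slope_limit <- function(nc) {
  if (any(nc <= 0)) stop("nc must be positive", call. = FALSE)
  1 / nc
}

#' Fit the genome-wide sweep rate across species
#'
#' Estimates the sweep rate `nuT` jointly with a linear map from body size
#' to baseline population size, `N0 = a + b * body_size`, by minimizing the
#' sum of squared differences between observed and predicted neutral
#' diversity across species (on the pi scale by default). The optimizer is
#' a seeded multi-start bounded local search; starts violating `N0 > 0`
#' for any species are penalized away. Ties are broken by lower SSQ, then
#' lower `nuT`.
#'
#' @param data Tibble with columns `species`, `pi_4d` (observed), `body_size`
#'   and `nc`.
#' @param mu Mutation rate (default 2.9e-9).
#' @param J Sweep kernel (default 1e-5).
#' @param UT Genome-wide deleterious mutation rate (default 0, sweep-only).
#' @param n_starts Number of optimizer starts (>= 1, default 10).
#' @param seed Seed for the start draws.
#' @param scale `"pi"` (default) or `"log"`: scale on which squared
#'   differences are accumulated.
#' @param proportional If `TRUE`, use the intercept-free map
#'   `N0 = b * body_size` instead of `a + b * body_size`.
#'
#' @return An object of class `sweep_fit`: list with `nuT_hat`,
#'   `body_coef` (intercept, slope), `ssq`, `predictions` tibble
#'   (per-species `pi_pred`, `N0`), `starts` tibble of all local optima.
#'   Methods: `tidy()`, `glance()`, `autoplot()`, [predicted_range()].
#' @export
fit_sweep_rate <- function(data, mu = 2.9e-9, J = 1e-5, UT = 0,
                           n_starts = 10, seed = 1,
                           scale = c("pi", "log"), proportional = FALSE) {
  scale <- match.arg(scale)
  stopifnot(all(c("pi_4d", "body_size", "nc") %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 species", call. = FALSE)
  if (any(data$body_size <= 0) || any(data$nc <= 0)) {
    stop("body sizes and chromosome numbers must be positive", call. = FALSE)
  }
  obs <- data$pi_4d
  size <- data$body_size
  nc <- data$nc

  n0_of <- function(par) {
    if (proportional) par[2] * size else par[1] + par[2] * size
  }
  objective <- function(par) {
    nuT <- par[length(par)]
    N0 <- n0_of(par)
    if (any(N0 <= 0) || nuT < 0) {
      return(1e12 + sum(pmax(0, -N0))^2 + max(0, -nuT))
    }
    pred <- expected_pi(N0 = N0, mu = mu, J = J, nuT = nuT, nc = nc, UT = UT)
    if (scale == "log") sum((log(obs) - log(pred))^2) else sum((obs - pred)^2)
  }

  # scale of N0 implied by the data if sweeps were absent
  n0_guess <- stats::coef(stats::lm(obs / (4 * mu) ~ size))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  starts <- purrr::map(seq_len(n_starts), function(i) {
    mult <- stats::runif(1, 0.5, 20) # sweeps depress pi, so true N0 >= naive
    a0 <- n0_guess[1] * mult
    b0 <- n0_guess[2] * mult
    nu0 <- stats::runif(1, 0, 1)
    if (proportional) {
      c(b = max(b0, 1), nuT = nu0)
    } else {
      c(a = a0, b = b0, nuT = nu0)
    }
  })
  fits <- purrr::map(starts, function(p0) {
    res <- stats::optim(p0, objective,
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-12)
    )
    # polish
    res <- stats::optim(res$par, objective,
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-14)
    )
    res
  })
  vals <- purrr::map_dbl(fits, "value")
  nus <- purrr::map_dbl(fits, function(f) f$par[length(f$par)])
  ord <- order(vals, nus)
  best <- fits[[ord[1]]]
  if (best$value >= 1e12) {
    stop("no feasible N0 map found (N0 <= 0 for some species at every ",
      "optimum); check body sizes or try proportional = TRUE",
      call. = FALSE
    )
  }
  par <- best$par
  nuT_hat <- max(0, par[length(par)])
  N0 <- n0_of(par)
  pred <- expected_pi(N0 = N0, mu = mu, J = J, nuT = nuT_hat, nc = nc, UT = UT)
  body_coef <- if (proportional) c(0, par[1]) else par[1:2]
  structure(
    list(
      nuT_hat = unname(nuT_hat),
      body_coef = unname(body_coef),
      ssq = best$value,
      mu = mu, J = J, UT = UT, scale = scale,
      predictions = tibble::tibble(
        species = if ("species" %in% names(data)) data$species else seq_along(obs),
        pi_obs = obs, body_size = size, nc = nc,
        N0 = unname(N0), pi_pred = unname(pred)
      ),
      starts = tibble::tibble(
        start = seq_len(n_starts),
        ssq = vals, nuT = nus
      )
    ),
    class = "sweep_fit"
  )
}

#' Range of diversity predicted by a sweep-rate fit
#'
#' The fitted sweep model compresses diversity differences between species;
#' comparing the max/min ratio of predicted against observed diversity
#' shows how much of the observed spread the model can generate.
#'
#' @param fit A [fit_sweep_rate()] object.
#' @return One-row tibble: `pred_min`, `pred_max`, `pred_ratio`,
#'   `obs_min`, `obs_max`, `obs_ratio`.
#' @export
predicted_range <- function(fit) {
  stopifnot(inherits(fit, "sweep_fit"))
  p <- fit$predictions
  tibble::tibble(
    pred_min = min(p$pi_pred), pred_max = max(p$pi_pred),
    pred_ratio = max(p$pi_pred) / min(p$pi_pred),
    obs_min = min(p$pi_obs), obs_max = max(p$pi_obs),
    obs_ratio = max(p$pi_obs) / min(p$pi_obs)
  )
}

#' @exportS3Method base::print
print.sweep_fit <- function(x, ...) {
  cat(sprintf(
    "Sweep-rate fit (n = %d species, %s scale)\n",
    nrow(x$predictions), x$scale
  ))
  cat(sprintf(
    "  nuT_hat = %.4g per generation; N0 = %.4g %+.4g * body_size; ssq = %.4g\n",
    x$nuT_hat, x$body_coef[1], x$body_coef[2], x$ssq
  ))
  invisible(x)
}

#' @export
tidy.sweep_fit <- function(x, ...) {
  tibble::tibble(
    term = c("nuT", "N0_intercept", "N0_slope"),
    estimate = c(x$nuT_hat, x$body_coef[1], x$body_coef[2])
  )
}

#' @export
glance.sweep_fit <- function(x, ...) {
  rng <- predicted_range(x)
  tibble::tibble(
    nuT_hat = x$nuT_hat, ssq = x$ssq, n = nrow(x$predictions),
    pred_ratio = rng$pred_ratio, obs_ratio = rng$obs_ratio
  )
}

#' @export
autoplot.sweep_fit <- function(object, ...) {
  dd <- tidyr::pivot_longer(object$predictions,
    cols = c("pi_obs", "pi_pred"),
    names_to = "which", values_to = "pi"
  )
  ggplot2::ggplot(dd, ggplot2::aes(
    x = .data$nc, y = .data$pi,
    colour = .data$which
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(pi_obs = "grey30", pi_pred = "firebrick"),
      labels = c(pi_obs = "observed", pi_pred = "predicted")
    ) +
    ggplot2::labs(
      x = "haploid chromosome number",
      y = expression(pi["4D"]),
      colour = NULL,
      title = sprintf("Sweep-rate fit: nuT = %.3f", object$nuT_hat)
    ) +
    ggplot2::theme_minimal()
}
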