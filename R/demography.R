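#' Per-window heterozygous-site profile of one diploid individual
#'
#' Cuts the callable sites of one individual into consecutive windows of a
#' fixed number of callable sites and counts heterozygous sites S per
#' window. For transcriptome data the windows are formed along the
#' concatenated classified sites (there are no contiguous genomic windows),
#' so a window is "1 kb of callable sequence" rather than a physical
#' interval. A trailing window shorter than `window_length` is dropped.
#'
#' @param geno Tibble with `pos` and a genotype column `gt` (or `gt_a`) for
#'   one individual; variant sites only, missing calls dropped from the
#'   callable universe.
#' @param classes Optional site classification (`pos`, `class`); when
#'   supplied, only positions classified `4D`, `0D` or `other` are
#'   callable, and `which_class` can restrict further.
#' @param window_length Callable sites per window (default 1000).
#' @param which_class Optional subset of classes to use (e.g. `"4D"`).
#'
#' @return An object of class `het_profile`: tibble (`window`, `length`,
#'   `s`) with attributes `mean_s`, `var_s`, `dispersion` (var/mean) and
#'   `null_var` (= `mean_s + mean_s^2`, the constant-size expectation).
#'   Methods: `glance()`, `autoplot()`.
#' @export
window_counts <- function(geno, classes = NULL, window_length = 1000,
                          which_class = NULL) {
  gt_col <- if ("gt" %in% names(geno)) "gt" else "gt_a"
  stopifnot(gt_col %in% names(geno), "pos" %in% names(geno))
  conf <- gt_config(geno[[gt_col]])
  geno <- geno[!conf %in% c("miss", "multi"), , drop = FALSE]
  conf <- conf[!conf %in% c("miss", "multi")]
  if (is.null(classes)) {
    callable <- sort(unique(geno$pos))
  } else {
    keep <- classes$class %in% (which_class %||% c("4D", "0D", "other"))
    callable <- sort(unique(classes$pos[keep]))
  }
  if (length(callable) < window_length) {
    stop("fewer callable sites (", length(callable), ") than one window",
      call. = FALSE
    )
  }
  het_pos <- geno$pos[conf == "het"]
  het_pos <- het_pos[het_pos %in% callable]
  n_win <- length(callable) %/% window_length
  win_of <- ceiling(seq_along(callable) / window_length)
  win_id <- win_of[match(het_pos, callable)]
  s <- tabulate(win_id[win_id <= n_win], nbins = n_win)
  new_het_profile(tibble::tibble(
    window = seq_len(n_win),
    length = window_length,
    s = s
  ))
}

# constructor shared with the simulators
new_het_profile <- function(windows) {
  m <- mean(windows$s)
  v <- stats::var(windows$s)
  structure(windows,
    class = c("het_profile", class(windows)),
    mean_s = m, var_s = v,
    dispersion = if (m > 0) v / m else NA_real_,
    null_var = constant_size_null(m)
  )
}

#' Variance of S expected under constant population size
#'
#' For a non-recombining window in a sample of two haplotypes from a
#' constant-size population, the pairwise coalescence time is exponential,
#' so S is geometrically distributed and `Var[S] = m + m^2` where `m` is
#' the mean. This exceeds the Poisson variance `m` that applies in the
#' limiting case of an extreme bottleneck or rapid growth, where
#' coalescence times are nearly deterministic.
#'
#' @param mean_S Mean heterozygous sites per window (>= 0).
#' @return Expected variance, vectorized.
#' @export
constant_size_null <- function(mean_S) {
  if (any(mean_S < 0)) stop("mean_S must be non-negative", call. = FALSE)
  mean_S + mean_S^2
}

#' Classify dispersion of window heterozygosity against the constant-size null
#'
#' Compares the observed variance of S across windows with the
#' distribution of variances obtained by a seeded parametric bootstrap
#' under the constant-size null (S geometric with the observed mean).
#' Windows whose variance falls above the upper tail are `OVERDISPERSED`
#' (signature of an intermediate bottleneck), below the lower tail
#' `UNDERDISPERSED` (towards the Poisson limit of extreme bottleneck or
#' growth), otherwise `CONSISTENT`.
#'
#' @param profile A [window_counts()] / simulator `het_profile` (>= 30
#'   windows).
#' @param reps Parametric-bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @param level Two-sided level of the interval (default 0.95).
#'
#' @return One-row tibble: `classification`, `mean_s`, `var_s`,
#'   `dispersion`, `null_var`, `null_low`, `null_high` (bootstrap interval
#'   for Var[S]), and `poisson_ratio` (= var/mean, 1 in the Poisson limit).
#' @export
dispersion_class <- function(profile, reps = 1000, seed = 1, level = 0.95) {
  stopifnot(inherits(profile, "het_profile"))
  n_win <- nrow(profile)
  if (n_win < 30) {
    stop("need at least 30 windows to classify dispersion", call. = FALSE)
  }
  m <- attr(profile, "mean_s")
  v <- attr(profile, "var_s")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- 1 / (1 + m) # geometric on 0,1,2,... with mean m
  boot_var <- vapply(seq_len(reps), function(i) {
    stats::var(stats::rgeom(n_win, p))
  }, numeric(1))
  a <- (1 - level) / 2
  qs <- stats::quantile(boot_var, c(a, 1 - a), names = FALSE)
  cls <- if (v > qs[2]) {
    "OVERDISPERSED"
  } else if (v < qs[1]) {
    "UNDERDISPERSED"
  } else {
    "CONSISTENT"
  }
  tibble::tibble(
    classification = cls,
    mean_s = m, var_s = v,
    dispersion = attr(profile, "dispersion"),
    null_var = attr(profile, "null_var"),
    null_low = qs[1], null_high = qs[2],
    poisson_ratio = attr(profile, "dispersion")
  )
}

#' @export
glance.het_profile <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x),
    mean_s = attr(x, "mean_s"),
    var_s = attr(x, "var_s"),
    dispersion = attr(x, "dispersion"),
    null_var = attr(x, "null_var")
  )
}

#' @export
autoplot.het_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "heterozygous sites per window (S)", y = "windows",
      title = sprintf(
        "Var[S] = %.2f, constant-size expectation %.2f",
        attr(object, "var_s"), attr(object, "null_var")
      )
    ) +
    ggplot2::theme_minimal()
}
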