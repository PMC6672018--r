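#' Seeded generators for synthetic study inputs
#'
#' Every generator takes an explicit `seed` and is deterministic given it.
#' Loci are unlinked and internally non-recombining; purifying selection
#' at zerofold sites is modelled as a multiplicative thinning of mutations
#' rather than explicit selective dynamics — enough to exercise the
#' diversity bookkeeping and the ratio regression, not a forward
#' simulation. Defaults follow the study conditions: two diploid
#' individuals per species, mutation rate `mu = 2.9e-9` per site per
#' generation, effective sizes of order 1e6.
#'
#' @name synthetic_data
#' @keywords internal
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- pair / small-sample coalescent under piecewise-constant Ne ----------

# epochs: tibble(size, start) with start[1] == 0, times in generations,
# sizes in diploids. Sizes may be ~0 to force coalescence at epoch start.
check_epochs <- function(epochs) {
  stopifnot(
    is.data.frame(epochs), all(c("size", "start") %in% names(epochs)),
    nrow(epochs) >= 1, epochs$start[1] == 0,
    !is.unsorted(epochs$start, strictly = TRUE), all(epochs$size >= 0)
  )
  if (any(epochs$size[-nrow(epochs)] == 0) &&
    epochs$size[nrow(epochs)] == 0 && nrow(epochs) == 1) {
    stop("degenerate epoch history", call. = FALSE)
  }
  epochs
}

# draw one coalescence waiting time for k lineages starting at time t0,
# under the piecewise-constant history; returns absolute time
piecewise_coal_time <- function(k, t0, epochs) {
  rate_scale <- choose(k, 2)
  e <- stats::rexp(1) # unit-exponential budget
  bounds <- c(epochs$start, Inf)
  i <- findInterval(t0, epochs$start)
  t <- t0
  repeat {
    N <- epochs$size[i]
    if (N <= 0) {
      return(max(t, epochs$start[i])) # instantaneous coalescence
    }
    rate <- rate_scale / (2 * N)
    span <- bounds[i + 1] - t
    if (e <= rate * span) {
      return(t + e / rate)
    }
    e <- e - rate * span
    t <- bounds[i + 1]
    i <- i + 1
  }
}

# genealogy of n_haps haplotypes: returns list of branches, each with the
# tip set it subtends and its length in generations
sim_genealogy <- function(n_haps, epochs) {
  active <- lapply(seq_len(n_haps), identity) # tip sets
  born <- rep(0, n_haps) # time each active lineage arose
  branches <- list()
  t <- 0
  while (length(active) > 1) {
    k <- length(active)
    t_next <- piecewise_coal_time(k, t, epochs)
    pair <- sample.int(k, 2)
    for (j in pair) {
      branches[[length(branches) + 1]] <- list(
        tips = active[[j]], length = t_next - born[j]
      )
    }
    merged <- c(active[[pair[1]]], active[[pair[2]]])
    active <- c(active[-pair], list(merged))
    born <- c(born[-pair], t_next)
    t <- t_next
  }
  branches
}

# --- pair genotype simulator ---------------------------------------------

#' Simulate a two-individual genotype dataset with site classes
#'
#' For each unlinked locus a random in-frame coding sequence (no internal
#' stops) is generated and classified by codon degeneracy; a 4-haplotype
#' genealogy is drawn under the piecewise-constant history; mutations fall
#' on branches as a Poisson process (infinite-sites: at most one mutation
#' per site) independently for each site class, with mutations at zerofold
#' sites retained only with probability `sel_reduction` — a diversity
#' thinning standing in for purifying selection. Haplotypes 1+2 form
#' individual A, 3+4 individual B.
#'
#' @param n_loci Number of unlinked loci.
#' @param locus_length Length of each coding sequence in bp (multiple of 3).
#' @param mu Mutation rate per site per generation.
#' @param epochs Population history, tibble with `size` (diploid N) and
#'   `start` (generations ago; first row 0). Default: constant 1e6.
#' @param sel_reduction Retention probability for zerofold mutations
#'   (default 0.1: non-synonymous diversity an order of magnitude below
#'   synonymous, as typical for insects).
#' @param seed Mandatory integer seed.
#'
#' @return List with `geno` (tibble `cds_id`, `pos`, `gt_a`, `gt_b`),
#'   `classes` (as [classify_cds()]), `cds` (named character vector of
#'   sequences), and `truth` (expected per-class diversity and the
#'   arguments).
#' @export
sim_pair_genotypes <- function(n_loci = 100, locus_length = 300,
                               mu = 2.9e-9,
                               epochs = tibble::tibble(size = 1e6, start = 0),
                               sel_reduction = 0.1, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(locus_length %% 3 == 0, n_loci >= 1)
  epochs <- check_epochs(epochs)
  set.seed(seed)
  sense_codons <- setdiff(
    names(Biostrings::GENETIC_CODE),
    c("TAA", "TAG", "TGA")
  )
  deg <- degeneracy_table()
  ids <- sprintf("locus%04d", seq_len(n_loci))
  seqs <- character(n_loci)
  class_list <- vector("list", n_loci)
  g_id <- g_pos <- g_a <- g_b <- vector("list", n_loci)
  for (l in seq_len(n_loci)) {
    codons <- sample(sense_codons, locus_length / 3, replace = TRUE)
    seqs[l] <- paste(codons, collapse = "")
    cls <- as.vector(rbind(
      deg[paste0(codons, 1)], deg[paste0(codons, 2)], deg[paste0(codons, 3)]
    ))
    class_list[[l]] <- cls
    branches <- sim_genealogy(4, epochs)
    blen <- vapply(branches, function(b) b$length, numeric(1))
    hap_mat <- vapply(
      branches,
      function(b) as.integer(1:4 %in% b$tips),
      integer(4)
    ) # 4 x n_branches carrier indicators
    pos_l <- integer(0)
    a_l <- b_l <- character(0)
    for (cl in c("4D", "0D", "other")) {
      sites <- which(cls == cl) - 1L # 0-based
      if (length(sites) == 0) next
      keep_p <- if (cl == "0D") sel_reduction else 1
      n_mut <- stats::rpois(1, mu * sum(blen) * length(sites) * keep_p)
      if (n_mut == 0) next
      n_mut <- min(n_mut, length(sites)) # infinite-sites guard
      mut_sites <- sample(sites, n_mut)
      mut_branch <- sample.int(length(branches), n_mut,
        replace = TRUE, prob = blen
      )
      carr <- hap_mat[, mut_branch, drop = FALSE]
      pos_l <- c(pos_l, mut_sites)
      a_l <- c(a_l, paste0(carr[1, ], "/", carr[2, ]))
      b_l <- c(b_l, paste0(carr[3, ], "/", carr[4, ]))
    }
    ord <- order(pos_l)
    g_id[[l]] <- rep(ids[l], length(pos_l))
    g_pos[[l]] <- pos_l[ord]
    g_a[[l]] <- a_l[ord]
    g_b[[l]] <- b_l[ord]
  }
  pi_neutral <- 4 * expected_pair_ne(epochs) * mu
  list(
    geno = tibble::tibble(
      cds_id = unlist(g_id),
      pos = unlist(g_pos),
      gt_a = unlist(g_a),
      gt_b = unlist(g_b)
    ),
    classes = tibble::tibble(
      cds_id = rep(ids, each = locus_length),
      pos = rep(0:(locus_length - 1L), n_loci),
      class = unname(unlist(class_list))
    ),
    cds = stats::setNames(seqs, ids),
    truth = list(
      pi_4d = pi_neutral,
      pi_0d = pi_neutral * sel_reduction,
      mu = mu, epochs = epochs, sel_reduction = sel_reduction, seed = seed
    )
  )
}

# E[T_pair] under the piecewise history (closed form), in units such that
# pi = 2 mu E[T]; expected_pair_ne returns E[T]/2 ("coalescent Ne")
expected_pair_ne <- function(epochs) {
  n <- nrow(epochs)
  bounds <- c(epochs$start, Inf)
  surv <- 1 # P(no coalescence before epoch start)
  et <- 0
  for (i in seq_len(n)) {
    N <- epochs$size[i]
    span <- bounds[i + 1] - bounds[i]
    if (N <= 0) {
      et <- et + surv * bounds[i]
      surv <- 0
      break
    }
    rate <- 1 / (2 * N)
    if (is.finite(span)) {
      p_in <- 1 - exp(-rate * span)
      # E[T | coalesce in epoch] contribution
      et <- et + surv * (p_in * bounds[i] +
        (1 / rate) * (1 - (1 + rate * span) * exp(-rate * span)))
      surv <- surv * (1 - p_in)
    } else {
      et <- et + surv * (bounds[i] + 1 / rate)
      surv <- 0
    }
  }
  et / 2
}

#' Simulate per-window heterozygous-site counts under a demographic history
#'
#' Each window is an unlinked, internally non-recombining stretch of `L`
#' callable sites in one diploid individual: a pairwise coalescence time T
#' is drawn from the piecewise-exponential law of the history and
#' `S ~ Poisson(2 T mu L)`. A single constant epoch gives geometric S
#' (`Var = m + m^2`); an instantaneous crash to size ~0 at time t makes T
#' deterministic and S Poisson; intermediate bottlenecks mix the two
#' scales and inflate the variance.
#'
#' @param n_windows Number of windows.
#' @param window_length Callable sites per window (default 1000).
#' @param mu Mutation rate per site per generation.
#' @param epochs History as in [sim_pair_genotypes()].
#' @param seed Mandatory seed.
#' @return A `het_profile` (see [window_counts()]) with a `truth`
#'   attribute (expected mean and the history).
#' @export
sim_bottleneck_windows <- function(n_windows = 1000, window_length = 1000,
                                   mu = 2.9e-9,
                                   epochs = tibble::tibble(size = 1e6, start = 0),
                                   seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  epochs <- check_epochs(epochs)
  set.seed(seed)
  t_coal <- vapply(
    seq_len(n_windows),
    function(i) piecewise_coal_time(2, 0, epochs),
    numeric(1)
  )
  s <- stats::rpois(n_windows, 2 * t_coal * mu * window_length)
  prof <- new_het_profile(tibble::tibble(
    window = seq_len(n_windows),
    length = window_length,
    s = s
  ))
  attr(prof, "truth") <- list(
    mean_s = 4 * expected_pair_ne(epochs) * mu * window_length,
    epochs = epochs, mu = mu, seed = seed
  )
  prof
}

#' Simulate a cross-species table under the sweep model
#'
#' Species body sizes are uniform on `size_range` (mm forewing length) and
#' chromosome numbers uniform integers on `nc_range`; the baseline
#' population size is linear in body size, `N0 = body_coef[1] +
#' body_coef[2] * size`; observed diversity is the sweep-model expectation
#' ([expected_pi()]) times lognormal noise `exp(N(0, sigma^2))`.
#'
#' @param n_species Number of species (default 38).
#' @param nuT True genome-wide sweep rate (default 0.133 per generation).
#' @param body_coef Intercept and slope of the N0-body-size map (defaults
#'   9e6 and -2e5 per mm: sizes 10-40 mm give N0 between 1e6 and 7e6,
#'   diversity spanning roughly 0.005-0.03 as observed in temperate
#'   butterflies).
#' @param size_range,nc_range Ranges for body size and chromosome number
#'   (defaults 10-40 mm and 13-31).
#' @param mu,J Model constants (defaults 2.9e-9 and 1e-5).
#' @param sigma Lognormal noise sd on pi (default 0.2).
#' @param seed Mandatory seed.
#' @return List: `data` tibble (`species`, `pi_4d`, `body_size`, `nc`) and
#'   `truth` (all parameters plus the noiseless `pi_true`).
#' @export
sim_species_table <- function(n_species = 38, nuT = 0.133,
                              body_coef = c(9e6, -2e5),
                              size_range = c(10, 40), nc_range = c(13, 31),
                              mu = 2.9e-9, J = 1e-5, sigma = 0.2, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(nuT >= 0, sigma >= 0)
  set.seed(seed)
  size <- stats::runif(n_species, size_range[1], size_range[2])
  nc <- sample(seq(nc_range[1], nc_range[2]), n_species, replace = TRUE)
  N0 <- body_coef[1] + body_coef[2] * size
  if (any(N0 <= 0)) {
    stop("body_coef implies non-positive N0 for some species", call. = FALSE)
  }
  pi_true <- expected_pi(N0 = N0, mu = mu, J = J, nuT = nuT, nc = nc)
  pi_obs <- pi_true * exp(stats::rnorm(n_species, 0, sigma))
  list(
    data = tibble::tibble(
      species = sprintf("sp%02d", seq_len(n_species)),
      pi_4d = pi_obs, body_size = size, nc = nc
    ),
    truth = list(
      nuT = nuT, body_coef = body_coef, mu = mu, J = J,
      sigma = sigma, pi_true = pi_true, N0 = N0, seed = seed
    )
  )
}

#' Simulate a Yule tree with a trait evolved under lambda-scaled Brownian motion
#'
#' @param n_tips Number of tips (>= 4).
#' @param lambda True phylogenetic signal in \[0, 1\]: trait covariance is
#'   the Brownian matrix with off-diagonals scaled by `lambda` (0 gives an
#'   i.i.d. trait, 1 plain Brownian motion).
#' @param sig2 Brownian rate (default 1).
#' @param birth Speciation rate of the pure-birth tree (default 1).
#' @param seed Mandatory seed.
#' @return List: `tree` (`phylo`), `trait` (named vector in tip order),
#'   `truth`.
#' @export
sim_tree_traits <- function(n_tips = 50, lambda = 1, sig2 = 1, birth = 1,
                            seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_tips >= 4, lambda >= 0, lambda <= 1)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  C <- ape::vcv(tree)
  V <- sig2 * lambda_transform(C, lambda)
  x <- drop(t(chol(V)) %*% stats::rnorm(n_tips))
  names(x) <- rownames(C)
  list(
    tree = tree, trait = x,
    truth = list(lambda = lambda, sig2 = sig2, seed = seed)
  )
}

#' Long-run divergence of two sequences under symmetric 4-allele mutation
#'
#' Evolves two initially identical sequences independently under the
#' symmetric (Jukes-Cantor-like) substitution model for many expected
#' substitutions per site and returns the realized per-site mismatch
#' fraction. As divergence time grows this saturates at the hard ceiling
#' `1 - 1/4 = 0.75`, the maximum possible nucleotide diversity without
#' mutational bias.
#'
#' @param n_sites Sequence length (default 1e5).
#' @param subs_per_site Expected substitutions per site per lineage
#'   (default 20: far past saturation).
#' @param seed Mandatory seed.
#' @return Realized mismatch fraction (a number near 0.75).
#' @export
sim_saturation_divergence <- function(n_sites = 1e5, subs_per_site = 20,
                                      seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  anc <- sample(1:4, n_sites, replace = TRUE)
  # given m jump events, the embedded chain gives
  # P(same base) = 1/4 + (3/4) (-1/3)^m exactly
  evolve <- function(x) {
    m <- stats::rpois(length(x), subs_per_site)
    p_same <- 1 / 4 + (3 / 4) * (-1 / 3)^m
    move <- stats::runif(length(x)) >= p_same
    out <- x
    idx <- which(move)
    shift <- sample(1:3, length(idx), replace = TRUE)
    out[idx] <- ((x[idx] - 1 + shift) %% 4) + 1
    out
  }
  a <- evolve(anc)
  b <- evolve(anc)
  mean(a != b)
}
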