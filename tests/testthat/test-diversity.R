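test_that("pi_b evaluates the between-individual formula", {
  counts <- tibble::tibble(n_a = 2, n_b = 2, n_ab = 0, n_fix = 1, n_tot = 100)
  expect_equal(pi_b(counts)$pi_b, 0.03)
  expect_equal(
    pi_b(tibble::tibble(n_a = 0, n_b = 0, n_ab = 0, n_fix = 0, n_tot = 50))$pi_b,
    0
  )
  # shared heterozygous sites weigh one half
  expect_equal(
    pi_b(tibble::tibble(n_a = 0, n_b = 0, n_ab = 4, n_fix = 0, n_tot = 100))$pi_b,
    0.02
  )
  # undefined, not zero, for an empty class
  expect_warning(
    res <- pi_b(tibble::tibble(n_a = 0, n_b = 0, n_ab = 0, n_fix = 0, n_tot = 0)),
    "undefined"
  )
  expect_true(is.na(res$pi_b))
})

test_that("pi_within is het/n_tot and equals twice the pi_b of private hets", {
  expect_equal(pi_within(3, 300), 0.01)
  expect_equal(pi_within(0, 10), 0)
  expect_warning(expect_true(is.na(pi_within(1, 0))))
  # algebra of the between-individual formula: het/2 vs het
  het <- 7
  n <- 220
  pb <- pi_b(tibble::tibble(n_a = het, n_b = 0, n_ab = 0, n_fix = 0, n_tot = n))
  expect_equal(pi_within(het, n), 2 * pb$pi_b)
})

test_that("count_site_classes matches brute-force enumeration on random toys", {
  for (seed in 1:10) {
    toy <- random_hap_toy(200, seed)
    got <- count_site_classes(toy$geno, toy$classes)
    got <- got[got$class == "4D", ]
    want <- brute_force_counts(toy$geno)
    expect_equal(got$n_a, want$n_a)
    expect_equal(got$n_b, want$n_b)
    expect_equal(got$n_ab, want$n_ab)
    expect_equal(got$n_fix, want$n_fix)
    expect_equal(got$n_tot, 200L)
  }
})

test_that("missing and multi-allelic calls leave the callable universe", {
  toy <- random_hap_toy(50, 3)
  geno <- toy$geno
  geno$gt_a[5] <- "./."
  geno$gt_b[10] <- "1/2" # multi-allelic
  got <- count_site_classes(geno, toy$classes)
  expect_equal(got$n_tot[got$class == "4D"], 48L)
  expect_equal(unname(attr(got, "dropped")["multiallelic"]), 1L)
  expect_equal(unname(attr(got, "dropped")["missing_call"]), 1L)
  # excluding sites never increases any count
  full <- count_site_classes(toy$geno, toy$classes)
  for (col in c("n_a", "n_b", "n_ab", "n_fix", "n_tot")) {
    expect_true(all(got[[col]] <= full[[col]]))
  }
})

test_that("pi_b equals the mean of the four inter-individual haplotype pairs", {
  for (seed in 1:20) {
    toy <- random_hap_toy(150, seed + 100)
    counts <- dplyr::filter(count_site_classes(toy$geno, toy$classes), class == "4D")
    got <- pi_b(counts)$pi_b
    expect_equal(got, inter_individual_pi(toy$haps))
  }
})

test_that("f_it behaves at the reference configurations", {
  # all fixed differences: no within-individual heterozygosity
  fixed <- tibble::tibble(gt_a = rep("0/0", 5), gt_b = rep("1/1", 5))
  expect_equal(f_it(fixed), 1)
  # one shared heterozygous site: maximal excess given unbiased H_exp
  shared <- tibble::tibble(gt_a = "0/1", gt_b = "0/1")
  expect_equal(f_it(shared), -0.5)
  # no polymorphism: undefined
  expect_warning(
    expect_true(is.na(f_it(tibble::tibble(gt_a = "0/0", gt_b = "0/0")))),
    "undefined"
  )
})

test_that("f_it centres on zero under random mating", {
  # draw genotypes as random unions of gametes at many sites
  set.seed(7)
  reps <- 200
  fits <- replicate(reps, {
    p <- runif(300, 0.1, 0.9)
    gt <- function() {
      h1 <- rbinom(300, 1, p)
      h2 <- rbinom(300, 1, p)
      paste0(h1, "/", h2)
    }
    suppressWarnings(f_it(tibble::tibble(gt_a = gt(), gt_b = gt())))
  })
  se <- sd(fits) / sqrt(reps)
  expect_lt(abs(mean(fits)), 4 * se + 0.01)
})

test_that("pairwise_pi averages haplotype mismatch, skipping gaps and N", {
  expect_equal(pairwise_pi(c("AAAA", "AAAT")), 0.25)
  expect_equal(pairwise_pi(c("ACGT", "ACGT", "ACGT")), 0)
  # N and gap positions are dropped pair-wise
  expect_equal(pairwise_pi(c("AANA", "AATT")), 1 / 3)
  expect_warning(expect_true(is.na(pairwise_pi(c("NNN", "AAA")))))
  # 4 haplotypes of a diploid pair: inter-individual restriction equals pi_b
  for (seed in 21:25) {
    toy <- random_hap_toy(100, seed)
    seqs <- apply(toy$haps, 1, function(h) {
      paste(c("A", "T")[h + 1], collapse = "")
    })
    counts <- dplyr::filter(count_site_classes(toy$geno, toy$classes), class == "4D")
    expect_equal(
      inter_individual_pi(toy$haps),
      pi_b(counts)$pi_b
    )
    # full pairwise pi over the 4 sequences also bounded by [0,1]
    expect_true(pairwise_pi(seqs) >= 0 && pairwise_pi(seqs) <= 1)
  }
})

test_that("estimate_diversity assembles per-class summaries", {
  sim <- sim_pair_genotypes(n_loci = 40, locus_length = 300, seed = 11)
  est <- estimate_diversity(sim$geno, sim$classes)
  expect_setequal(est$class, c("4D", "0D", "other"))
  expect_true(all(est$pi_b >= 0 & est$pi_b <= 0.75))
  expect_true(all(est$n_a + est$n_b + est$n_ab + est$n_fix <= est$n_tot))
  expect_true(is.numeric(attr(est, "f_it")))
})
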