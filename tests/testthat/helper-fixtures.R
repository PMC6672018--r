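# shared fixtures, built in code

# random phased 4-haplotype biallelic matrix and the matching genotype /
# classification tibbles; all sites labelled 4D so every site enters one class
random_hap_toy <- function(n_sites, seed) {
  set.seed(seed)
  haps <- matrix(rbinom(4 * n_sites, 1, runif(1, 0.1, 0.5)), nrow = 4)
  geno <- tibble::tibble(
    pos = 0:(n_sites - 1),
    gt_a = paste0(haps[1, ], "/", haps[2, ]),
    gt_b = paste0(haps[3, ], "/", haps[4, ])
  )
  classes <- tibble::tibble(
    pos = 0:(n_sites - 1),
    class = "4D"
  )
  list(haps = haps, geno = geno, classes = classes)
}

# mean pairwise difference over the four inter-individual haplotype pairs
inter_individual_pi <- function(haps) {
  pairs <- expand.grid(a = 1:2, b = 3:4)
  mean(apply(pairs, 1, function(ij) mean(haps[ij[1], ] != haps[ij[2], ])))
}

# brute-force per-site tally of the genotype configurations
brute_force_counts <- function(geno) {
  n_a <- n_b <- n_ab <- n_fix <- 0L
  for (i in seq_len(nrow(geno))) {
    a <- geno$gt_a[i]
    b <- geno$gt_b[i]
    a_het <- a %in% c("0/1", "1/0")
    b_het <- b %in% c("0/1", "1/0")
    if (a_het && b_het) {
      n_ab <- n_ab + 1L
    } else if (a_het) {
      n_a <- n_a + 1L
    } else if (b_het) {
      n_b <- n_b + 1L
    } else if (a != b) {
      n_fix <- n_fix + 1L
    }
  }
  list(n_a = n_a, n_b = n_b, n_ab = n_ab, n_fix = n_fix)
}
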