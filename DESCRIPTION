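Package: lepdiv
Title: Comparative Analysis of Genetic Diversity from Paired Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative population genomics with minimal sampling:
    two diploid individuals per species. Classifies coding positions by codon
    degeneracy, estimates synonymous and non-synonymous nucleotide diversity
    between and within individuals, fits the gamma shape of the distribution
    of fitness effects from the cross-species scaling of ln(pi0/pi4) with
    ln(pi4), implements an analytic model of neutral diversity under
    background selection and recurrent selective sweeps with chromosome-number
    scaling and a cross-species sweep-rate fit, provides a window-based
    heterozygosity-dispersion diagnostic of past demography, and computes
    phylogenetic-signal statistics (Pagel's lambda, family ANOVA, trait
    correlations). Includes seeded coalescent-based generators for all inputs
    so every stage can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    nlme,
    phytools,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
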