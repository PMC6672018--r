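# lepdiv

Comparative population genomics from minimal sampling: two diploid
individuals per species, coding sequence only. `lepdiv` is aimed at
researchers comparing genetic diversity across many taxa — the setting of
Lewontin's paradox, where neutral diversity varies far less than census
population size — and implements the full analysis chain from genotypes to
cross-species inference:

* **Site classes** — codon-degeneracy classification of coding positions
  (fourfold-degenerate 4D = putatively neutral, zerofold-degenerate 0D =
  amino-acid changing) under the standard genetic code.
* **Diversity** — between-individual diversity per site class,
  $\pi_b = \left[(n_A + n_B + n_{AB})/2 + n_{fix}\right] / n_{tot}$,
  within-individual heterozygosity, individual-vs-total differentiation
  $F_{IT}$, and a generic pairwise $\pi$ for loci such as mitochondrial
  barcodes.
* **DFE shape** — the gamma shape $\beta$ of the distribution of fitness
  effects, estimated as the negative slope of
  $\ln(\pi_{0D}/\pi_{4D})$ on $\ln(\pi_{4D})$ across species, with a
  seeded bootstrap CI.
* **Linked selection** — the analytic model
  $E[\pi] = \pi_0 / (8 N_0 J \nu_T n_c^{-1} + e^{4 U_T/n_c})$ for neutral
  diversity under recurrent sweeps (rate $\nu_T$) and background selection
  ($B = e^{-4 U_T/n_c}$), its chromosome-number scaling
  ($\partial \ln E[\pi]/\partial n_c \le 1/n_c$), and a cross-species fit
  of $\nu_T$ with baseline population size linear in body size.
* **Demography** — per-window heterozygous-site counts $S$ in one diploid
  individual, classified against the constant-size null
  $\mathrm{Var}[S] = m + m^2$ (geometric) by parametric bootstrap;
  Poisson-like $S$ indicates extreme bottleneck/growth, excess variance an
  intermediate bottleneck.
* **Phylogenetic statistics** — Pagel's $\lambda$ by maximum likelihood,
  one-way family ANOVA, Pearson correlations, Bonferroni helper.
* **Synthetic data** — seeded pair-coalescent, species-table, window and
  tree/trait generators emitting truth records, so every stage is testable
  without any external download.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for figures, and
`run_pipeline()` to drive the whole chain.

## Worked example

Simulate a pair of diploid individuals at 500 coding loci under a
constant population of $N_e = 10^6$ with $\mu = 2.9\times10^{-9}$
(so $4 N_e \mu = 0.0116$), and estimate diversity per site class:

```r
library(lepdiv)

sim <- sim_pair_genotypes(n_loci = 500, locus_length = 300, seed = 42)
est <- estimate_diversity(sim$geno, sim$classes)
est
#> # A tibble: 3 x 9
#>   class   n_a   n_b  n_ab n_fix n_tot    pi_b pi_within_a pi_within_b
#>   <chr> <int> <int> <int> <int> <int>   <dbl>       <dbl>       <dbl>
#> 1 4D      208   194   106    49 26260 0.0115      0.0120      0.0114
#> 2 0D       76    69    39    16 95075 0.00114     0.00121     0.00114
#> 3 other   233   230   114    54 28665 0.0119      0.0121      0.0120
attr(est, "f_it")
#> [1] -0.0092
```

Realized $\pi_{4D} = 0.0115$ sits at the neutral expectation, $\pi_{0D}$
is reduced tenfold (the simulated strength of purifying selection), and
$F_{IT} \approx 0$ reflects the panmictic simulation.

Fit the sweep rate to a simulated 38-species table (truth
$\nu_T = 0.133$, lognormal noise $\sigma = 0.2$):

```r
st  <- sim_species_table(n_species = 38, nuT = 0.133, sigma = 0.2, seed = 42)
fit <- fit_sweep_rate(st$data, seed = 1)
fit
#> Sweep-rate fit (n = 38 species, pi scale)
#>   nuT_hat = 0.107 per generation; N0 = 5.968e+06 -1.246e+05 * body_size; ssq = 0.0002412
glance(fit)
#> # A tibble: 1 x 5
#>   nuT_hat      ssq     n pred_ratio obs_ratio
#>     <dbl>    <dbl> <int>      <dbl>     <dbl>
#> 1   0.107 0.000241    38       3.00      4.76
```

The rate is recovered to ~20% under this noise level, and the fitted
model predicts a narrower diversity range (ratio 3.0) than observed
(4.8) — homogeneous linked selection compresses diversity differences
rather than creating them. Estimate the DFE shape from the same species:

```r
set.seed(42)
d   <- dplyr::mutate(st$data, pi_0d = 0.3 * pi_4d^(1 - 0.45) * exp(rnorm(38, 0, 0.15)))
dfe <- beta_slope(d, seed = 1)
dfe
#> Gamma-DFE shape from diversity-ratio scaling (OLS, n = 38)
#>   beta = 0.428  (95% bootstrap CI 0.283-0.604, 1000 reps)
```

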