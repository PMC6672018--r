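---
title: "Comparative diversity from paired transcriptomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative diversity from paired transcriptomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lepdiv)
```

`lepdiv` implements a comparative population-genomics workflow for taxa
sampled at the absolute minimum: two diploid individuals per species, with
coding sequence (typically transcriptome-derived) as the only sequence
resource. This vignette is the package's own account of the models behind
each stage, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not establish.

## Diversity from a pair of diploid individuals

Coding positions are classified by codon degeneracy under the standard
genetic code: fourfold-degenerate (4D) positions tolerate any nucleotide
without changing the protein and serve as the putatively neutral site
class; zerofold-degenerate (0D) positions change the amino acid under any
substitution. Positions of stop codons and codons containing ambiguity
codes are left unclassified and enter neither class. Codons carrying
segregating sites are classified against the reference codon only — with
two diploids, the reference and alternate codon rarely disagree about
degeneracy class, and a per-genotype reclassification would make the
callable universe sample-dependent.

Between-individual diversity for individuals A and B is

$$\pi_b = \frac{(n_A + n_B + n_{AB})/2 + n_{fix}}{n_{tot}},$$

where $n_A$ and $n_B$ count heterozygous sites private to each individual,
$n_{AB}$ shared heterozygous sites, $n_{fix}$ fixed homozygous differences,
and $n_{tot}$ the callable sites of the class. The formula is exactly the
mean of the four inter-individual haplotype comparisons — a property the
test suite verifies by brute-force enumeration on random phased toy data —
and is analogous to $d_{XY}$; computing diversity *between* individuals
sidesteps inbreeding within either one. A site enters $n_{tot}$ only when
both individuals carry a (biallelic) call; missing and multi-allelic
records are removed from the callable universe and tallied in a log
attribute rather than silently dropped.

Individual-versus-total differentiation is estimated as
$F_{IT} = 1 - \bar H_{obs} / \bar H_{exp}$ over polymorphic sites, with
$\bar H_{exp}$ the *unbiased* expected heterozygosity from the pooled
four-haplotype allele frequency (Nei's $n/(n-1)$ correction, here $4/3$).
With only four haplotypes the uncorrected ratio has expectation $-1/3$
under random mating; the corrected estimator centres on zero, which the
tests confirm by simulating random unions of gametes. The choice of
estimator matters at this sample size and is deliberately documented here:
other $F$-statistics (e.g. variance-decomposition estimators) would differ
in finite-sample behaviour.

A generic mean-pairwise-difference estimator (`pairwise_pi()`) covers loci
without degeneracy structure, such as a mitochondrial barcode alignment.

## DFE shape from the diversity-ratio scaling

Under the nearly neutral theory with gamma-distributed deleterious fitness
effects, the fraction of effectively neutral non-synonymous mutations
scales as $N_e^{-\beta}$, so across species

$$\ln(\pi_{0D}/\pi_{4D}) = c - \beta \ln(\pi_{4D}),$$

and the negative slope of the regression estimates the gamma shape
$\beta$. `beta_slope()` fits this by ordinary least squares; the 95%
interval is a seeded nonparametric bootstrap over species (percentile
method, 1000 replicates by default). OLS is the default because the
species-level analysis deliberately treats points as exchangeable — the
package's own phylogenetic-signal statistic shows neutral diversity
carries almost no tree structure in this kind of data — but a
`method = "gls"` mode with Brownian correlation from a supplied tree is
available for sensitivity analysis. Residuals above the fitted line flag
species where selection appears less efficient than their neutral
diversity predicts (recent bottlenecks, population structure);
`residual_rank()` orders them.

## Neutral diversity under background selection and sweeps

The analytic model treats selection at linked sites as homogeneous along
the genome:

$$E[\pi] = \frac{\pi_0}{2 N_0 J \nu / r_c + B^{-1}},
\qquad \pi_0 = 4 N_0 \mu,$$

with $B$ the background-selection factor, $\nu$ and $r_c$ the per-bp sweep
and recombination rates, and $J \approx s/[2\ln(2 N_e s)]$ the per-sweep
coalescence kernel for semi-dominant selection (valid only for
$2 N_e s > 1$; the function refuses the weakly selected domain). Scaling
rates per genome and proxying total map length by the haploid chromosome
number $n_c$ — about 50 cM per chromosome in male meiosis and no crossing
over in female Lepidoptera — gives $\nu/r \approx 4\nu_T/n_c$ and
$B \approx \exp(-4 U_T/n_c)$, hence

$$E[\pi] = \frac{\pi_0}{8 N_0 J \nu_T n_c^{-1} + e^{4 U_T / n_c}},$$

which reduces to $E[\pi]/\pi_0 = (8 N_0 J \nu_T n_c^{-1} + 1)^{-1}$ when
$U_T = 0$. Two consequences anchor the acceptance checks: for butterfly
karyotypes ($13 \le n_c \le 31$) and $U_T = 1$, $B$ stays within
0.73–0.88, so background selection alone cannot generate order-of-magnitude
diversity differences; and in the high-sweep-rate limit
$\partial \ln E[\pi] / \partial n_c = 1/n_c$, a maximum slope of 0.04 at
$n_c = 25$.

`fit_sweep_rate()` estimates the genome-wide sweep rate $\nu_T$ jointly
with a linear map $N_0 = a + b \cdot \text{body size}$ by minimizing the
sum of squared differences between observed and predicted $\pi_{4D}$.
Numerical choices:

* the objective is accumulated on the $\pi$ scale by default (a log-scale
  option exists for sensitivity analysis);
* the linear $N_0$ map is unconstrained in sign but any parameter vector
  giving $N_0 \le 0$ for a species is pushed away by a large penalty; an
  intercept-free proportional map (`proportional = TRUE`) is available
  because the exact linear form is a genuinely open choice at this level
  of abstraction;
* optimization is seeded multi-start Nelder–Mead (10 starts by default,
  relative tolerance $10^{-14}$ after polishing), with starts spread over
  multiples of the naive no-sweep $N_0$ regression since sweeps always
  depress diversity below $4 N_0 \mu$; ties break by lowest SSQ, then
  lowest $\nu_T$;
* defaults $\mu = 2.9\times10^{-9}$ and $J = 10^{-5}$ follow the constants
  used in the butterfly analysis this package operationalizes, and
  $U_T = 0$ makes the default fit sweep-only.

Identifiability comes from the transition region of the hyperbola: with
$8 N_0 J \nu_T / n_c$ of order one — which the realistic parameter ranges
produce — $\nu_T$ and the $N_0$ map separate cleanly. Noiseless synthetic
tables are recovered to well under 1% relative error; the fitted model
systematically predicts a *narrower* diversity range than observed
(`predicted_range()`), which is precisely the model's scientific point:
homogeneous linked selection compresses, rather than explains, the spread.

## Heterozygosity dispersion as a demographic diagnostic

For one diploid individual, cut the callable sites into windows of fixed
callable length (default 1000 sites — transcriptome data have no
contiguous physical windows, so a window is "1 kb of callable sequence"
along the concatenated classified positions) and count heterozygous sites
$S$ per window. For a non-recombining window the pair coalescence time in
a constant-size population is exponential, making $S$ geometric:
$\mathrm{Var}[S] = m + m^2$ for mean $m$. An extreme bottleneck (or rapid
growth) makes coalescence times nearly deterministic and $S$ Poisson
($\mathrm{Var} = m$); an intermediate bottleneck mixes two coalescence
scales and inflates the variance beyond the geometric null.
`dispersion_class()` compares the observed variance against a seeded
parametric bootstrap of geometric windows at the observed mean (1000
replicates, two-sided 95% interval) rather than a χ² dispersion index,
because the null is geometric, not Poisson. The null ignores
recombination *within* windows, which in real data pulls $S$ towards
Poisson; the test is therefore conservative for overdispersion calls and
anti-conservative for underdispersion calls — a stated limitation, not a
bug, and one reason the Poisson-limit ratio is reported alongside the
classification.

## Phylogenetic signal and cross-species statistics

`pagel_lambda()` maximizes the Brownian-motion Gaussian likelihood with
off-diagonal covariances scaled by $\lambda \in [0, 1]$, profiling the
mean and rate analytically at each $\lambda$ (GLS via Cholesky solves) and
optimizing the 1-D profile with `optimize()` at tolerance $10^{-6}$,
always comparing the interior optimum against both boundaries. The
p-value is a likelihood-ratio test against $\lambda = 0$ on χ²(1). Because
$\lambda = 0$ lies on the boundary of the parameter space, the textbook
mixture convention would halve this p-value; the plain χ²(1) convention
used here is conservative, and either convention returns $p = 1$ when the
estimate itself is at zero — the situation this diagnostic exists to
detect. A star phylogeny makes the likelihood flat in $\lambda$; the fit
is flagged (`NA` with a warning) instead of returning an arbitrary
number. An independent implementation (`phytools::phylosig`) is used as a
cross-check in the test suite, never as the estimator.

Family effects and trait associations use the classical machinery —
`stats::aov` behind `anova_oneway()`, `stats::cor.test` behind
`pearson_cor()` — exposed with tidy one-row outputs, plus a Bonferroni
helper for multi-predictor screens. Bivariate Bayesian phylogenetic mixed
models are deliberately out of scope; where a tree-aware regression is
wanted, the GLS mode of `beta_slope()` is the documented, clearly more
modest substitute.

## What the synthetic data emulate — and what they do not

The generators produce every input the pipeline consumes, deterministically
given a mandatory seed:

* `sim_pair_genotypes()` draws, per unlinked locus, a 4-haplotype
  genealogy under a piecewise-constant population history (exact
  piecewise-exponential waiting times), drops infinite-sites mutations on
  branches, and emits genotypes, a random in-frame CDS with its degeneracy
  classification, and the analytic truth ($\pi_{4D} = 4 N_e \mu$ for the
  constant history). Purifying selection at 0D sites is a mutation
  *thinning* (default retention 0.1, matching the order-of-magnitude
  $\pi_{0D}/\pi_{4D}$ gap typical of insects), not selective dynamics.
* `sim_bottleneck_windows()` gives per-window $S$ under a chosen epoch
  history; a final epoch of size ~0 forces coalescence and realizes the
  Poisson limit exactly.
* `sim_species_table()` builds 38-species tables from the sweep model with
  $N_0$ linear in body size (defaults: sizes 10–40 mm, $n_c$ 13–31,
  intercept $9\times10^6$, slope $-2\times10^5$ per mm, so $N_0$ spans
  1–7 million and diversity roughly 0.005–0.03, the realistic range for
  temperate butterflies), times lognormal noise with $\sigma = 0.2$.
* `sim_tree_traits()` grows a pure-birth tree (`ape::rphylo`) and draws a
  trait from the $\lambda$-scaled Brownian covariance.

Consequently, passing tests establish internal consistency — estimators
recover the parameters of the generating models at the stated rates — but
not robustness to features the generators omit: intra-locus recombination,
linked selection in the sequence simulator (sweep effects live only in the
analytic module), base-composition and mutation-spectrum heterogeneity,
mapping and genotyping error, and reference bias. Those caveats transfer
directly to any real-data application.

## Problem sizes and degenerate inputs

The test suite and the acceptance script scale simulations to sizes the
estimators' Monte-Carlo error makes informative: 1500–6000 loci of 300 bp
for pair-coalescent checks (3 standard errors around $4 N_e \mu$), 20–50
replicate 38-species tables for recovery and coverage rates, 200–3000
windows for dispersion calibration, and 50 replicate 50-tip trees for
signal recovery. Degenerate inputs are signalled, not coerced: diversity
with $n_{tot} = 0$ is `NA` with a warning (undefined, distinct from zero),
$F_{IT}$ without polymorphism likewise, empty sequences and histories with
mis-ordered epochs are errors, and every generator refuses to run without
a seed.
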