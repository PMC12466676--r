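---
title: "Methods: animal models under heterogeneity of variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: animal models under heterogeneity of variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical methods implemented in varhet
and the design decisions behind them. Code chunks are illustrative and
not evaluated during build; the same computations run (with small
designs) in the package's test suite.

## 1. Record preparation

Total milk yield `tmp` over a lactation of `ll` days is adjusted to a
305-day basis by the linear rule

\[ \mathrm{MP305} = \mathrm{TMP} + b\,(305 - \mathrm{LL}), \]

with the slope either fixed at the historical value 5.47111 kg/day
(`mode = "replication"`) or re-estimated from the data by regressing
yield on lactation length (`mode = "reestimate"`).

The expected-heterozygosity covariate for an animal with sire breed
fraction \(s\) and dam breed fraction \(d\) is
\( \mathrm{HTZ} = s(1-d) + (1-s)d \), the probability that one random
allele from each parent forms a mixed-breed pair.

Calving months map to quarterly seasons (Jan–Mar = 1, …, Oct–Dec = 4).
A contemporary group (CG) is a herd × calving-year × season cell; CGs
with fewer than 3 records are discarded. Each retained CG is assigned a
phenotypic-variability class by standardizing CG mean yields across CGs:
standardized mean ≤ 0 gives LOW, > 0 gives HIGH. Classes are attributes
of the CG, so no animal has records in both classes (one record per
animal).

## 2. Pedigree machinery

Pedigrees are validated (no duplicate animals, parents precede
offspring, no cycles) and sorted so ancestors come first. The numerator
relationship matrix \(A\) is built by the tabular method; its inverse is
assembled directly and sparsely from Henderson's rules using
Mendelian-sampling variances that account for parental inbreeding,
with inbreeding coefficients from the tabular diagonal. `a_inverse()`
agrees with `solve(relationship_matrix()$A)` to 1e-8 on random
pedigrees (tested).

## 3. Models

The general analysis is the single-trait animal model

\[ y = X\beta + Za + e, \qquad a \sim N(0, A\sigma^2_a), \quad
   e \sim N(0, I\sigma^2_e), \]

where \(X\) carries CG fixed effects, the HTZ covariate and the
(centred) age-at-calving covariate.

The by-class analysis treats yield in the LOW and HIGH classes as two
traits:

\[ y_t = X_t\beta_t + Z_t a_t + e_t, \quad t \in \{L, H\}, \qquad
   \begin{pmatrix} a_L \\ a_H \end{pmatrix}
   \sim N\!\left(0,\; G_0 \otimes A\right). \]

Because record sets are disjoint by animal, the residual covariance
between classes is inestimable and fixed at 0, as in standard
multiple-trait analyses with non-overlapping record sets.

## 4. Gibbs sampler

Full conditionals are standard: normal for each location effect,
scaled inverse chi-square for each residual variance (degrees of
freedom \(n_t + \nu_e\)), scaled inverse chi-square for the single-trait
genetic variance (\(q + \nu_a\)), and inverse-Wishart for \(G_0\)
(\(q + \nu_g\), scale \(S_a + S_g\) with
\(S_a = [a_s' A^{-1} a_t]_{st}\)), sampled through a Bartlett
decomposition.

Location effects are updated by a single-site Gauss–Seidel scan.
Additionally, every `block_every` cycles (default 10) the full genetic
vector — both traits jointly in the bivariate model — is redrawn in one
exact multivariate-normal block using a sparse Cholesky factorisation
of the genetic-block precision \(Z'Z/\sigma^2_e + G_0^{-1} \otimes
A^{-1}\). The sparsity pattern is fixed across cycles, so the symbolic
analysis is performed once and each block move only refills values and
refactorises. Both moves draw from exact full conditionals of the same
joint posterior, so the stationary distribution is unchanged.

The block move is not an optional optimisation: single-site updates of a
pedigree-correlated vector of several thousand effects cannot traverse
the small-genetic-variance region of the posterior in any practical
number of cycles (the vector must shrink or grow one coordinate at a
time against the prior correlation), which manifests as an absorbing
collapse of \(\sigma^2_{a}\) for one trait and a genetic correlation
pinned at ±1. With periodic joint redraws the sampler reproduces, on
mid-scale test problems, the posterior obtained from an independent
dense-matrix reference implementation that redraws all locations jointly
every cycle.

### Priors

Variance priors default to the flat convention \(\nu_0 = -2,\ S_0 = 0\):
the scaled inverse chi-square density is then constant in
\(\sigma^2\), and the conditional reduces to
\(\mathrm{SSE}/\chi^2_{n-2}\). For the 2×2 genetic covariance matrix the
default is \(\nu_g = -(p+1) = -3,\ S_g = 0\), which makes the
inverse-Wishart density exponent \(-(\nu_g+p+1)/2\) vanish: the prior is
uniform over positive-definite matrices, the exact matrix analogue of
the flat univariate convention.

Two superficially similar choices fail in practice and are deliberately
avoided (both remain reachable through `gibbs_priors()` for
experimentation):

* A proper inverse-Wishart with small scale (\(\varepsilon I\), minimal
  degrees of freedom) concentrates density \(\propto |G_0|^{-3}\) near
  singular matrices. Once the chain visits a nearly singular
  \(G_0\), the conditional regenerates it — a quasi-absorbing state that
  pins the genetic correlation at ±1.
* \(\nu_g = -2\) (flat marginals on both genetic variances) has density
  \(\propto |G_0|^{-1/2}\), which diverges (integrably) at singular
  \(G_0\) and creates a spurious posterior mode at
  \(\sigma^2_{a} \approx 0\).

Draw retention: cycle \(c\) (1-indexed) is kept iff \(c > \text{burnin}\)
and \((c - \text{burnin}) \bmod \text{thin} = 0\).

## 5. Posterior summaries and diagnostics

`posterior_summary()` reports posterior mean, Monte-Carlo standard
error, SD, median and the equal-tailed 95% credible interval for every
variance component and derived parameter
(\(h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_e)\) per class, and
\(r_g = \sigma_{a,LH}/\sqrt{\sigma^2_{a,L}\sigma^2_{a,H}}\)).

The Geweke diagnostic compares the means of the first 10% and last 50%
of the chain with spectral variance estimates from batch means,
\(z = (\bar x_1 - \bar x_2)/\sqrt{\widehat{s}_1/n_1 + \widehat{s}_2/n_2}\).
On IID chains \(|z| \ge 1.96\) occurs for ~5% of replicates (calibrated
in the tests over 1,000 chains).

## 6. Detecting heterogeneity of variance

`compare_analyses()` combines:

* a two-sided Z-test comparing posterior heritability means between the
  LOW and HIGH classes;
* overlap of the 95% credible intervals for \(\sigma^2_a\) and
  \(\sigma^2_e\) between classes;
* Spearman rank correlations of sire EBVs between the general and
  class-specific analyses (all sires, and the subset with positive
  general EBVs, where re-ranking matters for selection);
* regressions of general-analysis EBVs on class-specific EBVs, whose
  slopes show how the general analysis compresses or stretches the
  scale of the best sires.

## 7. Synthetic data

`simulate_dataset()` draws CG effects from a scaled, centred gamma (so
CG means have realistic spread and skew), breeding-value pairs from
\(N(0, G_0 \otimes A)\) via generation-ordered Mendelian sampling with
parental-inbreeding-corrected variances, and phenotypes as
CG effect + covariates + \(a_{\text{class}}\) + residual, with the
record's trait chosen by its CG's class. Classes are *emergent* by
default — the generator labels CGs by the sign of their simulated
standardized means, and the analysis recomputes labels from the data —
or *forced* (random labels) for clean two-trait recovery experiments.
TMP is back-computed from MP305 so that preprocessing recovers the
intended yields exactly.

```{r example}
library(varhet)
sim <- simulate_dataset(sim_config(), seed = 1)
prep <- prepare_records(sim$records, mode = "replication")
rs <- a_inverse(sim$pedigree)
dl <- build_design(prep, sim$pedigree$animal, "LOW")
dh <- build_design(prep, sim$pedigree$animal, "HIGH")
fit <- gibbs_bivariate(dl, dh, rs$Ainv, chain_config(60000, 6000, 20, seed = 1))
posterior_summary(fit, "by_class")
```

## 8. Estimator behaviour at realistic scale

With ~2,400 records over ~160 CGs and 77 sire families, the sampling
spread of the high-class heritability estimate is large: restricted
maximum likelihood on the same simulated designs has a per-replicate SD
of ~0.10 (this is an information bound of the design, not a sampler
property). Posterior means additionally sit slightly above the REML
mode because the marginal posterior of a variance component under flat
priors is right-skewed. Recovery experiments therefore compare
*cross-seed medians* of posterior means against the truth, not single
replicates.
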