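---
title: "Methods: negative binomial mutation burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: negative binomial mutation burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model, the estimation procedure, the
numerical choices and the validation design behind `mutburden`. It is a
methods reference, not a tutorial; see the README for a worked example.

## The model

### Why not binomial or Poisson

The constant-rate baseline treats every base pair as an independent
Bernoulli trial with a genome-wide success probability
`lambda = total mutations / usable genome length`, so an element of length
`l_k` carrying `y_k` mutations is scored with a binomial (or, in the
rare-event limit, Poisson) upper tail. Somatic mutation rates, however, vary
several-fold along the genome and across patients, so real per-bin counts
have variance far above their mean. Under the constant-rate model the
variance is forced to equal the mean, every excess-variance bin looks like a
signal, and the screen's type-I error is grossly inflated. The package keeps
the baseline (`fit_global_rate()`, `binomial_tail_pvalue()`) only as a
comparison point and provides `ks_overdispersion()` to demonstrate the
misfit on any catalog.

### Gamma–Poisson mixture

Counts are pooled per disease in bins of length `l` (default 1 Mb) on a
fixed genome grid. Patient heterogeneity is modelled hierarchically: sample
`j`'s rate in bin `i` is Gamma-distributed, and its count is Poisson given
the rate. Summing independent Gammas over the `s_d` samples of a disease
gives a pooled rate `Lambda_i ~ Gamma(shape = 1/sigma, scale = mu_i * sigma)`
and a pooled count with the negative binomial marginal

```
P(y) = (1 + sigma * mu)^(-1/sigma)
       * Gamma(y + 1/sigma) / (Gamma(1/sigma) * Gamma(y + 1))
       * (sigma * mu / (1 + sigma * mu))^y
```

with mean `mu` and variance `mu * (1 + mu * sigma)`. `sigma` measures
population-level rate heterogeneity: `sigma -> 0` recovers the Poisson, and
the implementation switches to the exact Poisson expressions below
`sigma = 1e-8`. `nb_pmf()` evaluates this in log space via `lgamma`, and the
test suite verifies it against adaptive quadrature of the mixture integral
to 1e-8.

### Covariate regression

The local mean is regressed on genomic covariates with a log link:
`log(mu_i) = beta' x_i`. Covariates (chromatin signal, replication timing,
GC content, and similar tracks) are averaged over bins with *mean0*
semantics — uncovered bases count as 0, so the denominator is always the
full bin length — replicate tracks are averaged, and the matrix is
standardized and rotated by PCA (`fit_pca()`) because such tracks are
strongly collinear. All PCs are used by default; `rank_pcs()` orders them by
mean absolute correlation with counts when a truncated model is wanted.

Estimation (`fit_nb_regression()`) alternates two steps until the
log-likelihood changes by less than `tol * (|ll| + 1)`:

* given `sigma`, an iteratively reweighted least squares update of `beta`
  with weights `w_i = mu_i / (1 + sigma * mu_i)` — the exact NB Fisher
  information for the log link;
* given `beta`, a one-dimensional profile maximization of `sigma` by
  `optimize()` on `log(sigma)` over `[log(1e-8), log(100)]`.

Initialization uses the Poisson GLM for `beta` and the method-of-moments
`sigma_0 = max(1e-4, (s^2 - ybar) / ybar^2)`. Standard errors come from
`(X' W X)^{-1}`. With `constant_sigma = FALSE` the dispersion itself gets a
log-linear covariate model, fitted jointly by BFGS; the constant-`sigma`
model is the default because the dispersion is a population property and a
per-bin dispersion model is rarely identifiable at desk scale.

### Region tests

A candidate region of summed length `l_k` (multi-interval regions such as
merged gene transcripts share a `name`) is scored against
`mu_k = mu_bin * l_k / l`, where `mu_bin` comes from either

* the **approximation scheme** (default): the prediction of the usable
  training bin whose centre is nearest the region midpoint, or
* the **optimal scheme**: a fresh prediction from covariates recomputed on
  an `l`-length window centred on the region (shifted, not truncated, at
  chromosome ends).

`sigma` is carried over unadjusted: under the mixture reading it measures
between-patient heterogeneity, which does not shrink with region length.
The p-value is the NB upper tail `P(Y >= y_k)`, computed stably via the
Beta-function identity `pbeta(sigma*mu/(1+sigma*mu), y, 1/sigma)` (the
Poisson path uses `pgamma(mu, shape = y)`), floored at 1e-300.
Benjamini–Hochberg correction is applied within disease and annotation
class. Across diseases, and across the `M` member genes of a pathway,
p-values combine with Fisher's method, `T = -2 * sum(log p)` against a
chi-square with `2 D` (or `2 M`) degrees of freedom; missing members reduce
the degrees of freedom, and floored zeros are counted in the output.

## Coordinates and formats

Internally everything is 0-based half-open (BED convention). Tabular and
VCF variant positions are 1-based on disk and converted on read. Promoter
and TSS windows are strictly upstream of the first transcribed base:
`[start - L, start)` on the plus strand, `[end, end + L)` on the minus
strand, with `L = 2500` and `L = 100` by default. Standard formats go
through established parsers: `rtracklayer` for bedGraph/GTF, `Biostrings`
for FASTA, `vcfR` for VCF, `GenomicRanges` for interval overlap; BH is
`stats::p.adjust` and the PCA core is `stats::prcomp` (with a deterministic
sign convention: the largest-magnitude loading of each PC is positive).

## The synthetic generator

`simulate_dataset()` emulates the study conditions end to end so that every
pipeline stage can be validated without external data:

* a small genome (default four 125 Mb chromosomes, 1 Mb grid, 500 bins);
* `m = 8` covariate tracks from a rank-3 latent factor model
  `X = F L' + noise` (`noise_sd = 0.5`), reproducing the collinearity of
  real chromatin tracks that motivates the PCA step;
* true means `mu_i = exp(beta0 + beta' x_std,i)` on the standardized
  covariates, with `beta0 = log(150)` giving a realistic ~150 mutations
  per Mb per disease;
* per-sample Gamma rates and Poisson counts (`sigma = 0.2`, 50 samples,
  2 diseases by default), scattered uniformly within bins.

The generator covers rate heterogeneity, covariate structure and pooling.
It does **not** emulate sequence context (no trinucleotide signatures),
mapping artifacts, copy-number variation, or selection; conclusions about
those require real catalogs.

`permute_variants()` implements the local permutation null: each variant
moves to a uniform position within ±50 kb (clipped at chromosome ends),
which destroys element-scale clustering while preserving regional rates,
chromosome totals and sample labels.

## Validation design

The acceptance suite (`tests/testthat/test-acceptance.R`) checks properties
rather than headline numbers, since the latter depend on full-scale
catalogs. Two designs deserve explanation:

**Calibration regions.** Null calibration is checked on 10^4 regions of
20–100 kb. At the default background (~150 mutations/Mb) these have
`mu_k` of roughly 3–15, large enough that the discrete NB tail can actually
achieve sizes near 0.05; kilobase-scale regions (`mu_k` ~ 0.1) cannot, and
any empirical type-I band would be vacuous there. The Q–Q/KS check uses
randomized p-values `u = P(Y > y) + U * P(Y = y)`, which are exactly
Uniform(0,1) under the null, removing discreteness from the comparison.

**Hotspot injection.** Recovery and the permutation null trade off: the
permuted catalog spreads each element's injected mass over a ±50 kb window,
so long elements retain enough local elevation after permutation to trip
the test, while short elements have too little null power for recovery.
The chosen design — 800 background + 40 hotspot elements of 2 kb, with
injected extra counts of mean `39 * mu_k + 10` (at least a 10-fold, always
> 3-fold, elevation) — gives near-certain per-hotspot recovery (expected
counts >= 12 against nulls of `mu_k` ~ 0.1–0.9) while the permuted leak per
element is under 0.9 expected mutations, keeping the probability of any
BH-significant element under the global null at the few-percent level that
BH itself guarantees.

## Limitations

* The NB variance law is quadratic in `mu`; mutational processes with even
  heavier tails (localized hypermutation, kataegis) will still inflate the
  test and should be masked or modelled upstream.
* The approximation scheme assumes covariates vary slowly at the bin scale;
  regions in rapidly varying neighbourhoods should use the optimal scheme.
* Fisher combination assumes independence across diseases and across
  pathway members; shared samples or overlapping regions violate it.
* `sigma` is held constant genome-wide by default; the varying-dispersion
  model is available but needs substantially more data per covariate.
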