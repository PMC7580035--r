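# mutburden

Negative binomial regression for somatic mutation burden analysis.

Cancer genomes accumulate somatic mutations at rates that vary by orders of
magnitude along the genome (chromatin state, replication timing, GC content)
and across patients. A test that assumes a single constant mutation rate —
the binomial/Poisson baseline — badly underestimates this variance and
floods any regional burden screen with false positives. `mutburden` instead
models pooled per-bin mutation counts as a Gamma–Poisson mixture: each
sample's local rate is Gamma-distributed around a bin-level mean, so the
pooled count is marginally negative binomial with mean `mu` and variance
`mu * (1 + mu * sigma)`. The bin-level mean is regressed (log link) on
principal components of genomic covariate tracks, and candidate regions —
genes, promoters, TSS windows, enhancers — are then tested for excess
mutation against their length-adjusted local expectation, with
Benjamini–Hochberg correction and Fisher combination across diseases or
pathway members.

The package is tidyverse-native: inputs and outputs are tibbles, models have
`tidy()`, `glance()`, `predict()` and `autoplot()` methods, and everything
composes with pipes.

## Worked example

The package ships a synthetic-data generator that emulates a desk-scale
whole-genome study: 4 chromosomes of 125 Mb on a 1 Mb grid (500 training
bins), 8 covariate tracks sharing 3 latent factors, and an overdispersed
(`sigma = 0.2`) mutation catalog of 50 samples.

```r
library(mutburden)

sim <- simulate_dataset(synthetic_config(diseases = "D1"), seed = 1)
nrow(sim$catalog)
#> [1] 116920

counts <- count_mutations(sim$catalog, sim$bins)
y <- counts$y[order(counts$bin)]
summary(y)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>     5.0    68.0   134.0   233.8   272.5  3755.0
```

Counts per 1 Mb bin range from 5 to 3755 — far wider than Poisson. The KS
diagnostic confirms a constant-rate model cannot fit:

```r
ks_overdispersion(y, bin_length = 1e6, reps = 100, seed = 2)
#> <ks_report> 100 replicates over 500 bins; lambda_hat = 0.0002338; median KS = 0.636
```

Correct for covariates with PCA, then fit the NB regression:

```r
pca <- fit_pca(sim$covariates)
tidy(pca)
#> # A tibble: 8 × 4
#>      pc  sdev explained_variance_ratio cumulative
#>   <int> <dbl>                    <dbl>      <dbl>
#> 1     1 2.19                    0.601       0.601
#> 2     2 1.24                    0.191       0.793
#> 3     3 0.919                   0.105       0.898
#> # …

fit <- fit_nb_regression(pca$scores, y)
glance(fit)
#> # A tibble: 1 × 6
#>    nobs logLik sigma pearson converged n_iter
#>   <int>  <dbl> <dbl>   <dbl> <lgl>      <int>
#> 1   500 -2774. 0.189   0.867 TRUE           3
```

The fit recovers the generating overdispersion (`sigma = 0.189`, truth 0.2)
and predicts observed counts with Pearson r = 0.867. Now test candidate
regions — here one with 60 extra mutations injected into a 50 kb window and
one untouched:

```r
regions <- tibble::tibble(
  chrom = "chrS1",
  start = c(2.05e6, 7.4e6), end = c(2.1e6, 7.45e6),
  name  = c("elemA", "elemB")
)
set.seed(1)
hot <- tibble::tibble(chrom = "chrS1",
                      pos = 2.05e6 + floor(runif(60) * 5e4),
                      sample = "sX", disease = "D1")

burden_test(regions, dplyr::bind_rows(sim$catalog, hot), fit, sim$bins)
#> # A tibble: 2 × 12
#>   name  class  chrom   start     end length disease     y    mu sigma        p
#> 1 elemA region chrS1 2050000 2100000  50000 D1         77  10.2 0.189 4.52e-10
#> 2 elemB region chrS1 7400000 7450000  50000 D1         51  35.3 0.189 1.67e- 1
```

The injected element is flagged (p = 4.5e-10); the untouched element, despite
carrying more raw mutations than expected genome-wide average, is correctly
explained by its local background (p = 0.17). Multi-disease results combine
with `combine_diseases()` (Fisher's method), pathway-level burden with
`network_pvalue()` and GMT gene sets, and `autoplot()` methods draw Q–Q,
calibration and observed-vs-predicted plots.

Real data enters through `read_variants()` (tabular or VCF),
`read_bedgraph()` tracks, `read_gtf_genes()` +
`derive_promoters_tss()`/`merge_transcripts()` annotations, and
`make_bins()`/`apply_blacklist()` grids. A command-line pipeline covering
simulate → grid → covariates → train → test → combine → network → diagnose →
annotate is installed at `inst/cli/mutburden.R`.

## Testing

```sh
Rscript -e 'devtools::test()'
```

The suite includes unit tests with independent numerical oracles
(quadrature of the Gamma–Poisson mixture, brute-force interval enumeration,
`MASS::glm.nb` cross-checks) and end-to-end statistical acceptance tests
(calibration, hotspot recovery, permutation null, baseline inflation).

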