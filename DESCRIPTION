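Package: mutburden
Title: Negative Binomial Regression for Somatic Mutation Burden Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests genomic regions and gene networks for excess somatic
    mutation. Pooled per-bin mutation counts are modelled as a
    Gamma-Poisson mixture (marginally negative binomial) to absorb
    mutation-rate heterogeneity across patients, and the local background
    rate is regressed on PCA-transformed genomic covariates (chromatin
    signal, replication timing, GC content). Region-level means are
    length-adjusted, upper-tail p-values are Benjamini-Hochberg corrected
    and combined across diseases or pathway members with Fisher's method.
    Includes binomial/Poisson constant-rate baselines, a variant
    permutation null, a Kolmogorov-Smirnov overdispersion diagnostic and
    a synthetic-data generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
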