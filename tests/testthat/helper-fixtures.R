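# Small in-code fixtures shared across test files.

toy_bins <- function(sizes = c(chrA = 3e6, chrB = 1e6), l = 1e6) {
  make_bins(sizes, l)
}

# a variant catalog placed deterministically at given (chrom, pos) triples
toy_catalog <- function(chrom, pos, sample = "s1", disease = "d1") {
  tibble::tibble(chrom = chrom, pos = pos,
                 sample = rep_len(sample, length(pos)),
                 disease = rep_len(disease, length(pos)))
}

# independent quadrature oracle for the Gamma-Poisson marginal:
# integral of dpois(y | lambda) * dgamma(lambda; shape 1/sigma, scale mu*sigma)
nb_pmf_quadrature <- function(y, mu, sigma) {
  shape <- 1 / sigma
  scale <- mu * sigma
  upper <- stats::qgamma(1 - 1e-13, shape = shape, scale = scale)
  vapply(y, function(yy) {
    stats::integrate(
      function(lam) stats::dpois(yy, lam) *
        stats::dgamma(lam, shape = shape, scale = scale),
      lower = 0, upper = max(upper, 1e-6),
      rel.tol = 1e-11, abs.tol = 1e-13, subdivisions = 2000L
    )$value
  }, numeric(1))
}

# randomized ("uniformized") p-value for discrete upper-tail tests:
# exactly Uniform(0,1) when y is drawn from the null pmf
randomized_tail_p <- function(y, mu, sigma) {
  p_ge <- nb_tail_pvalue(y, mu, sigma)
  p_gt <- p_ge - nb_pmf(y, mu, sigma)
  pmax(pmin(p_gt + stats::runif(length(y)) * (p_ge - p_gt), 1), 0)
}

# non-overlapping random test regions inside usable bins
sample_regions <- function(bins, n, len_range = c(20e3, 100e3)) {
  usable <- dplyr::filter(bins, usable)
  idx <- sample.int(nrow(usable), n, replace = TRUE)
  len <- round(stats::runif(n, len_range[1], len_range[2]))
  start <- usable$start[idx] +
    floor(stats::runif(n) * (usable$end[idx] - usable$start[idx] - len))
  tibble::tibble(
    chrom = usable$chrom[idx],
    start = pmax(start, usable$start[idx]),
    end = pmax(start, usable$start[idx]) + len,
    name = paste0("r", seq_len(n))
  )
}
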