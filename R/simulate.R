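#' Configuration for the synthetic mutation dataset
#'
#' Bundles the study conditions the generator emulates: a small genome on a
#' fixed grid, correlated covariate tracks driven by a latent low-rank
#' factor field, per-disease regression coefficients on the standardized
#' covariates, Gamma-distributed per-sample rates and Poisson counts.
#'
#' Defaults mimic a desk-scale whole-genome study: four 125 Mb chromosomes
#' on a 1 Mb grid (500 training bins), 8 covariate tracks sharing 3 latent
#' factors (chromatin-like collinearity), two diseases of 50 samples each,
#' moderate overdispersion (`sigma = 0.2`) and a background of roughly 150
#' mutations per bin per disease.
#'
#' @param chrom_sizes Named vector of synthetic chromosome lengths.
#' @param bin_length Training bin length `l`.
#' @param n_features Number of covariate tracks `m`.
#' @param latent_rank Rank of the latent factor model generating correlated
#'   covariates.
#' @param noise_sd SD of independent noise added on top of the factors.
#' @param diseases Character vector of disease labels.
#' @param samples_per_disease Samples `s_d` pooled per disease (recycled).
#' @param beta Coefficient matrix `(1 + n_features) x D` (intercept first)
#'   applied to the standardized covariates; a single vector is recycled
#'   across diseases.
#' @param sigma True overdispersion per disease (recycled).
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(chrom_sizes = c(chrS1 = 125e6, chrS2 = 125e6,
                                             chrS3 = 125e6, chrS4 = 125e6),
                             bin_length = 1e6,
                             n_features = 8,
                             latent_rank = 3,
                             noise_sd = 0.5,
                             diseases = c("D1", "D2"),
                             samples_per_disease = 50,
                             beta = NULL,
                             sigma = 0.2) {
  D <- length(diseases)
  if (is.null(beta)) {
    beta <- rbind(log(150),
                  matrix(rep_len(c(0.4, -0.25, 0.15, -0.1, 0.2, -0.15, 0.1,
                                   -0.05), n_features), ncol = 1))
    beta <- beta[, rep(1, D), drop = FALSE]
  }
  if (is.vector(beta)) beta <- matrix(beta, ncol = 1)[, rep(1, D), drop = FALSE]
  stopifnot(nrow(beta) == n_features + 1, ncol(beta) == D)
  structure(
    list(
      chrom_sizes = chrom_sizes, bin_length = bin_length,
      n_features = n_features, latent_rank = latent_rank,
      noise_sd = noise_sd, diseases = diseases,
      samples_per_disease = rep_len(samples_per_disease, D),
      beta = beta, sigma = rep_len(sigma, D)
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic dataset of covariate tracks and somatic variants
#'
#' Emulates the full input stack of a burden analysis. Covariate values per
#' bin come from a rank-`r` latent factor model (`X = F L' + noise`),
#' rendered as per-bin bedGraph-style step tracks. True per-bin means are
#' `mu_i^d = exp(beta0 + beta' x_std,i)` on the standardized covariates.
#' Each sample's rate in each bin is drawn
#' `Gamma(shape = 1/(sigma * s_d), scale = mu * sigma)`, counts are Poisson
#' given the rate, and variants are scattered uniformly within their bin —
#' so pooled per-bin counts are marginally negative binomial
#' (`mu`, `sigma`).
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; the catalog is byte-identical under the same
#'   seed and configuration.
#' @return A list: `bins`, `covariates` (tibble `bin` + features), `tracks`
#'   (named list of bedGraph tibbles), `catalog` (tibble `chrom`, `pos`,
#'   `sample`, `disease`), and `truth` (`beta`, `sigma`, `mu` matrix
#'   n x D, standardized design `x_std`).
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  bins <- make_bins(config$chrom_sizes, config$bin_length)
  n <- nrow(bins)
  m <- config$n_features
  r <- config$latent_rank
  fac <- matrix(stats::rnorm(n * r), n, r)
  load <- matrix(stats::rnorm(m * r), m, r)
  X <- fac %*% t(load) + config$noise_sd * matrix(stats::rnorm(n * m), n, m)
  colnames(X) <- paste0("f", seq_len(m))
  x_std <- scale(X)
  mu <- exp(cbind(1, x_std) %*% config$beta)  # n x D
  if (any(!is.finite(mu)) || any(mu > 1e9)) {
    stop("simulated mean overflow; rescale the coefficients", call. = FALSE)
  }
  colnames(mu) <- config$diseases

  catalog <- purrr::map_dfr(seq_along(config$diseases), function(d) {
    s_d <- config$samples_per_disease[d]
    sg <- config$sigma[d]
    purrr::map_dfr(seq_len(s_d), function(s) {
      lam <- if (sg < 1e-12) mu[, d] / s_d else
        stats::rgamma(n, shape = 1 / (sg * s_d), scale = mu[, d] * sg)
      y <- stats::rpois(n, lam)
      idx <- rep.int(seq_len(n), y)
      if (length(idx) == 0) return(NULL)
      tibble::tibble(
        chrom = bins$chrom[idx],
        pos = bins$start[idx] +
          floor(stats::runif(length(idx)) * config$bin_length),
        sample = sprintf("%s_s%03d", config$diseases[d], s),
        disease = config$diseases[d]
      )
    })
  })
  covariates <- dplyr::bind_cols(tibble::tibble(bin = bins$bin),
                                 tibble::as_tibble(X))
  tracks <- purrr::map(stats::setNames(seq_len(m), colnames(X)), function(j) {
    tibble::tibble(chrom = bins$chrom, start = bins$start, end = bins$end,
                   value = X[, j])
  })
  list(
    bins = bins,
    covariates = covariates,
    tracks = tracks,
    catalog = catalog,
    truth = list(beta = config$beta, sigma = config$sigma, mu = mu,
                 x_std = x_std, config = config)
  )
}

#' Permutation null: relocate each variant within +-50 kb
#'
#' Destroys element-scale clustering while preserving the regional mutation
#' rate: every variant is independently moved to a uniform position within
#' `window` bp on either side of its original position (original position
#' included), clipped at chromosome ends; chromosome, sample and disease
#' are preserved, as are per-chromosome variant totals.
#'
#' @param catalog Variant tibble (`chrom`, `pos`, `sample`, `disease`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window Half-window in bp (default 50,000, i.e. a 100 kb
#'   neighbourhood).
#' @param seed Optional integer seed.
#' @return Permuted catalog, same number of rows.
#' @export
permute_variants <- function(catalog, chrom_sizes, window = 50000,
                             seed = NULL) {
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes[[2]]), chrom_sizes[[1]])
  }
  if (!is.null(seed)) set.seed(seed)
  len <- chrom_sizes[catalog$chrom]
  if (any(is.na(len))) {
    stop("catalog chromosomes absent from `chrom_sizes`", call. = FALSE)
  }
  lo <- pmax(0, catalog$pos - window)
  hi <- pmin(len - 1, catalog$pos + window)
  catalog$pos <- lo + floor(stats::runif(nrow(catalog)) * (hi - lo + 1))
  catalog
}

#' Kolmogorov-Smirnov diagnostic of count overdispersion
#'
#' Checks whether observed per-bin counts are compatible with a constant
#' per-position rate. The constant-rate MLE `lambda_hat` (total count /
#' total bp) is fitted, then for each of `reps` replicates `n` Poisson
#' counts with mean `lambda_hat * bin_length` are drawn and the two-sample
#' KS statistic against the observed counts recorded. KS statistics near 0
#' mean the constant-rate model fits; statistics bounded away from 0 across
#' all replicates indicate overdispersion.
#'
#' @param y Observed per-bin counts for one disease.
#' @param bin_length Bin length `l` in bp.
#' @param reps Number of simulation replicates (default 100).
#' @param seed Optional integer seed.
#' @return A `ks_report`: list with `statistics` (tibble `rep`,
#'   `statistic`), `lambda_hat`, `n`, `reps`.
#' @export
ks_overdispersion <- function(y, bin_length, reps = 100, seed = NULL) {
  check_counts(y)
  n <- length(y)
  if (n < 2) stop("need at least two bins", call. = FALSE)
  if (sum(y) == 0) stop("all counts are zero", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lambda_hat <- sum(y) / (n * bin_length)
  stat <- vapply(seq_len(reps), function(i) {
    sim <- stats::rpois(n, lambda_hat * bin_length)
    unname(suppressWarnings(stats::ks.test(y, sim)$statistic))
  }, numeric(1))
  structure(
    list(
      statistics = tibble::tibble(rep = seq_len(reps), statistic = stat),
      lambda_hat = lambda_hat,
      n = n,
      reps = reps
    ),
    class = "ks_report"
  )
}

#' @export
print.ks_report <- function(x, ...) {
  cat("<ks_report> ", x$reps, " replicates over ", x$n,
      " bins; lambda_hat = ", format(x$lambda_hat, digits = 4),
      "; median KS = ", format(stats::median(x$statistics$statistic),
                               digits = 3), "\n", sep = "")
  invisible(x)
}

#' @method tidy ks_report
#' @export
tidy.ks_report <- function(x, ...) x$statistics

#' @method glance ks_report
#' @export
glance.ks_report <- function(x, ...) {
  tibble::tibble(
    lambda_hat = x$lambda_hat, n = x$n, reps = x$reps,
    median_ks = stats::median(x$statistics$statistic),
    min_ks = min(x$statistics$statistic),
    max_ks = max(x$statistics$statistic)
  )
}
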