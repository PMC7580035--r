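#' Negative binomial probability mass from the Gamma-Poisson mixture
#'
#' Probability of observing `y` pooled mutations when per-sample mutation
#' rates are Gamma-distributed across patients and counts are conditionally
#' Poisson. Marginally the count is negative binomial with mean `mu` and
#' overdispersion `sigma`, so that `Var = mu * (1 + mu * sigma)`:
#'
#' \deqn{P(y) = \left(\frac{1}{1+\sigma\mu}\right)^{1/\sigma}
#'   \frac{\Gamma(y + 1/\sigma)}{\Gamma(1/\sigma)\,\Gamma(y+1)}
#'   \left(\frac{\sigma\mu}{1+\sigma\mu}\right)^{y}}
#'
#' Evaluation is in log space via log-gamma; `sigma` below `1e-8` takes the
#' exact Poisson limit.
#'
#' @param y Non-negative integer count(s).
#' @param mu Mean `mu >= 0` (expected mutations per unit).
#' @param sigma Overdispersion `sigma >= 0`; 0 degenerates to Poisson.
#' @param log Return log probabilities?
#'
#' @return Numeric vector of probabilities.
#' @export
nb_pmf <- function(y, mu, sigma, log = FALSE) {
  check_counts(y)
  stopifnot(all(mu >= 0), all(sigma >= 0))
  n <- max(length(y), length(mu), length(sigma))
  y <- rep_len(y, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  lp <- numeric(n)
  pois <- sigma < 1e-8
  if (any(pois)) {
    lp[pois] <- stats::dpois(y[pois], mu[pois], log = TRUE)
  }
  if (any(!pois)) {
    yy <- y[!pois]; m <- mu[!pois]; s <- sigma[!pois]
    r <- 1 / s
    lp[!pois] <- -r * log1p(s * m) +
      lgamma(yy + r) - lgamma(r) - lgamma(yy + 1) +
      yy * (log(s) + log(m) - log1p(s * m))
    # mu == 0: point mass at zero
    zero_mu <- m == 0
    lp[!pois][zero_mu] <- ifelse(yy[zero_mu] == 0, 0, -Inf)
  }
  if (log) lp else exp(lp)
}

check_counts <- function(y) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  invisible(y)
}

#' Upper-tail burden p-value under the negative binomial model
#'
#' `P(Y >= y_obs)` for the mixture of [nb_pmf()] — the one-sided excess test
#' used for every region. Computed through the regularized incomplete beta
#' function (the NB survival identity), which is stable far into the tail;
#' results below `1e-300` are floored for downstream logarithms.
#'
#' @inheritParams nb_pmf
#' @param y_obs Observed count(s); `y_obs = 0` returns exactly 1.
#' @return p-value(s) in `(0, 1]`.
#' @export
nb_tail_pvalue <- function(y_obs, mu, sigma) {
  check_counts(y_obs)
  stopifnot(all(mu >= 0), all(sigma >= 0))
  n <- max(length(y_obs), length(mu), length(sigma))
  y <- rep_len(y_obs, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  p <- numeric(n)
  zero <- y == 0
  p[zero] <- 1
  pois <- !zero & sigma < 1e-8
  # Poisson survival P(Y >= y) = P(Gamma(y, 1) <= mu)
  p[pois] <- stats::pgamma(mu[pois], shape = y[pois])
  nb <- !zero & !pois
  # NB survival P(Y >= y) = I_{sm/(1+sm)}(y, 1/sigma)
  p[nb] <- stats::pbeta(sigma[nb] * mu[nb] / (1 + sigma[nb] * mu[nb]),
                        y[nb], 1 / sigma[nb])
  pmax(p, 1e-300)
}

#' Draw pooled counts from the Gamma-Poisson sampling model
#'
#' Simulates the generative story directly: each of `s_d` samples gets an
#' independent Gamma rate with shape `1/(sigma * s_d)` and scale
#' `mu * sigma`; rates are summed over samples and a Poisson count is drawn.
#' The marginal distribution of the pooled count equals [nb_pmf()]
#' with parameters (`mu`, `sigma`) regardless of `s_d`.
#'
#' @param n Number of draws.
#' @param mu,sigma NB mean and overdispersion (scalars or length-`n`).
#' @param s_d Number of samples pooled per draw.
#' @return Integer vector of pooled counts of length `n`.
#' @export
sample_gamma_poisson <- function(n, mu, sigma, s_d = 1) {
  stopifnot(n >= 1, s_d >= 1)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  pois <- sigma < 1e-12
  lambda <- numeric(n)
  if (any(pois)) lambda[pois] <- mu[pois]
  if (any(!pois)) {
    m <- mu[!pois]; s <- sigma[!pois]
    # sum of s_d iid Gamma(1/(s*s_d), m*s) rates = Gamma(1/s, m*s)
    tot <- rowSums(matrix(
      stats::rgamma(sum(!pois) * s_d, shape = 1 / (s * s_d), scale = m * s),
      ncol = s_d
    ))
    lambda[!pois] <- tot
  }
  stats::rpois(n, lambda)
}

#' Genome-wide constant mutation rate (MLE)
#'
#' Maximum-likelihood per-position rate under a constant-rate model:
#' total mutation count divided by the usable genome length. The same value
#' serves as the Poisson rate `lambda` and the binomial per-base success
#' probability `p` of the global baseline models.
#'
#' @param n_mutations Total mutation count for one disease.
#' @param usable_length Usable genome length in bp.
#' @return Per-position rate (double).
#' @export
fit_global_rate <- function(n_mutations, usable_length) {
  if (usable_length <= 0) stop("usable length must be positive", call. = FALSE)
  n_mutations / usable_length
}

#' Upper-tail p-value of the constant-rate binomial baseline
#'
#' `P(Y >= y_obs)` under `Binomial(n, p)` with per-base rate `p` — the
#' global baseline, or the local variant with `p = mu / l` (the
#' length-normalized regression mean). Kept as the comparison model whose
#' inflation under overdispersion motivates the mixture.
#'
#' @param y_obs Observed count(s).
#' @param n Region length in bp.
#' @param p Per-base mutation probability in `[0, 1]`.
#' @return p-value(s).
#' @export
binomial_tail_pvalue <- function(y_obs, n, p) {
  check_counts(y_obs)
  if (any(p < 0) || any(p > 1)) {
    stop("per-base rate `p` must lie in [0, 1]", call. = FALSE)
  }
  len <- max(length(y_obs), length(n), length(p))
  y <- rep_len(y_obs, len); n <- rep_len(n, len); p <- rep_len(p, len)
  out <- ifelse(y == 0, 1,
                stats::pbinom(pmin(y, n + 1) - 1, n, p, lower.tail = FALSE))
  pmax(out, 0)
}

#' Relative prediction error of the background rate
#'
#' Per bin, `|mu_obs - mu_pred| / mu_obs`; the summary over bins is the mean
#' by default (median available). Bins with `mu_obs = 0` carry no
#' information about relative error and are skipped with a warning.
#'
#' @param mu_obs Observed per-bin counts/rates.
#' @param mu_pred Predicted values, same length.
#' @param aggregate `"mean"`, `"median"`, or `"none"` for the per-bin vector.
#' @return A single number, or the per-bin vector for `aggregate = "none"`.
#' @export
relative_error <- function(mu_obs, mu_pred,
                           aggregate = c("mean", "median", "none")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(mu_obs) == length(mu_pred))
  keep <- mu_obs > 0
  if (any(!keep)) {
    warning(sum(!keep), " bin(s) with zero observed value skipped",
            call. = FALSE)
  }
  e <- abs(mu_obs[keep] - mu_pred[keep]) / mu_obs[keep]
  switch(aggregate, mean = mean(e), median = stats::median(e), none = e)
}
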