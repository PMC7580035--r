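#' Negative binomial regression of mutation counts on PC covariates
#'
#' Maximum-likelihood fit of the Gamma-Poisson (negative binomial) model
#' with a log link on the mean: `mu_i = exp(beta' x_i)` where `x_i` is the
#' i-th row of `x` with an intercept prepended. In the production setting
#' the overdispersion `sigma` is a single constant across bins
#' (`constant_sigma = TRUE`), estimated by profile likelihood alternating
#' with iteratively reweighted least squares updates of `beta`. Setting
#' `constant_sigma = FALSE` additionally regresses `log(sigma_i)` on the
#' same covariates (coefficients `alpha`), fitted by quasi-Newton
#' optimization from the constant-sigma solution.
#'
#' Initialization: `beta` from a Poisson log-linear fit, `sigma` from the
#' method-of-moments estimate `max(1e-4, (s^2 - ybar) / ybar^2)`.
#'
#' @param x Covariate matrix or tibble (typically PC scores), one row per
#'   bin, without an intercept column. A `bin` column is ignored.
#' @param y Non-negative integer counts, one per row of `x`.
#' @param constant_sigma Keep `sigma` constant across bins (default,
#'   production setting)?
#' @param max_iter Maximum outer iterations (default 200).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#'
#' @return An object of class `nb_regression`: coefficients `beta` (named,
#'   incl. `(Intercept)`), `alpha` (log-sigma model; a lone intercept in
#'   constant-sigma mode), `sigma` (fitted constant, or per-bin vector),
#'   `fitted` (mu-hat), `loglik`, `converged`, `n_iter`, `se_beta`.
#' @export
fit_nb_regression <- function(x, y, constant_sigma = TRUE,
                              max_iter = 200, tol = 1e-8) {
  if (is.data.frame(x)) {
    if ("bin" %in% names(x)) x <- dplyr::select(x, -"bin")
    x <- as.matrix(x)
  }
  check_counts(y)
  stopifnot(nrow(x) == length(y))
  if (!all(is.finite(x))) stop("non-finite covariates", call. = FALSE)
  if (sum(y) == 0) stop("all counts are zero; nothing to fit", call. = FALSE)
  X <- cbind("(Intercept)" = 1, x)
  if (is.null(colnames(x))) {
    colnames(X)[-1] <- paste0("x", seq_len(ncol(x)))
  }

  # Poisson initialization for beta
  beta <- stats::glm.fit(X, y, family = stats::poisson())$coefficients
  ybar <- mean(y)
  sigma <- max(1e-4, (stats::var(y) - ybar) / ybar^2)

  ll <- nb_loglik(X, y, beta, sigma)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    beta <- nb_irls_beta(X, y, beta, sigma)
    opt <- stats::optimize(
      function(ls) nb_loglik(X, y, beta, exp(ls)),
      interval = c(log(1e-8), log(100)), maximum = TRUE, tol = 1e-10
    )
    sigma <- exp(opt$maximum)
    ll_new <- opt$objective
    if (is.finite(ll) && abs(ll_new - ll) < tol * (abs(ll) + 1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) {
    warning("NB regression did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  eta <- drop(X %*% beta)
  mu <- exp(pmin(eta, 700))
  w <- mu / (1 + sigma * mu)
  se_beta <- sqrt(diag(solve(crossprod(X, w * X))))
  fit <- structure(
    list(
      beta = stats::setNames(beta, colnames(X)),
      alpha = c("(Intercept)" = log(sigma)),
      sigma = sigma,
      constant_sigma = TRUE,
      fitted = mu,
      loglik = ll,
      converged = converged,
      n_iter = iter,
      se_beta = stats::setNames(se_beta, colnames(X)),
      n = length(y),
      y = y
    ),
    class = "nb_regression"
  )
  if (constant_sigma) {
    return(fit)
  }
  nb_fit_varying_sigma(X, y, fit, max_iter)
}

# log-likelihood of the NB(mu, sigma) model; sigma scalar or per-bin
nb_loglik <- function(X, y, beta, sigma) {
  eta <- drop(X %*% beta)
  if (any(eta > 700)) return(-Inf)
  sum(nb_pmf(y, exp(eta), sigma, log = TRUE))
}

# one full IRLS pass (iterated to convergence) for beta at fixed sigma;
# weights w = mu / (1 + sigma * mu) are the NB Fisher weights for log link
nb_irls_beta <- function(X, y, beta, sigma, inner_max = 50) {
  for (i in seq_len(inner_max)) {
    eta <- drop(X %*% beta)
    mu <- exp(pmin(eta, 700))
    w <- mu / (1 + sigma * mu)
    z <- eta + (y - mu) / mu
    beta_new <- drop(solve(crossprod(X, w * X), crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < 1e-10 * (1 + max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# joint quasi-Newton fit of (beta, alpha) with log(sigma_i) = alpha' x_i,
# warm-started from the constant-sigma solution
nb_fit_varying_sigma <- function(X, y, init, max_iter) {
  p <- ncol(X)
  start <- c(init$beta, init$alpha[1], rep(0, p - 1))
  negll <- function(par) {
    beta <- par[1:p]; alpha <- par[(p + 1):(2 * p)]
    eta <- drop(X %*% beta)
    lsig <- drop(X %*% alpha)
    if (any(eta > 700) || any(abs(lsig) > 50)) return(1e12)
    -sum(nb_pmf(y, exp(eta), exp(lsig), log = TRUE))
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = max_iter * 5, reltol = 1e-10))
  beta <- stats::setNames(opt$par[1:p], colnames(X))
  alpha <- stats::setNames(opt$par[(p + 1):(2 * p)], colnames(X))
  mu <- exp(pmin(drop(X %*% beta), 700))
  sigma <- exp(drop(X %*% alpha))
  structure(
    list(
      beta = beta, alpha = alpha, sigma = sigma, constant_sigma = FALSE,
      fitted = mu, loglik = -opt$value, converged = opt$convergence == 0,
      n_iter = init$n_iter, se_beta = init$se_beta, n = length(y), y = y
    ),
    class = "nb_regression"
  )
}

#' @export
print.nb_regression <- function(x, ...) {
  cat("<nb_regression> n =", x$n, "bins;",
      length(x$beta) - 1, "covariates; logLik =", format(x$loglik), "\n")
  cat("  sigma:", if (x$constant_sigma) format(x$sigma) else "covariate-dependent",
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Predict background means from a fitted burden model
#'
#' @param object An `nb_regression` fit.
#' @param newdata New covariate rows (same columns as training, no
#'   intercept); omit for fitted values.
#' @param ... Unused.
#' @return Vector of predicted means `mu`.
#' @export
predict.nb_regression <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (is.data.frame(newdata)) {
    if ("bin" %in% names(newdata)) newdata <- dplyr::select(newdata, -"bin")
    newdata <- as.matrix(newdata)
  }
  X <- cbind(1, newdata)
  exp(pmin(drop(X %*% object$beta), 700))
}

#' @method tidy nb_regression
#' @export
tidy.nb_regression <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se_beta),
    statistic = unname(x$beta / x$se_beta),
    p.value = 2 * stats::pnorm(-abs(unname(x$beta / x$se_beta)))
  )
}

#' @method glance nb_regression
#' @export
glance.nb_regression <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    logLik = x$loglik,
    sigma = if (x$constant_sigma) x$sigma else NA_real_,
    pearson = stats::cor(x$y, x$fitted),
    converged = x$converged,
    n_iter = x$n_iter
  )
}
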