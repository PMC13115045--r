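#' Fit competitor lifetime models to a complete sample
#'
#' Maximum likelihood fits of the Log-Logistic, Weibull, Lognormal and
#' Exponential distributions to a complete (uncensored) positive sample.
#' Lognormal and Exponential have closed-form MLEs; Weibull and
#' Log-Logistic are maximised numerically (the latter via
#' [fit_loglogis()]).
#'
#' @param data vector of positive observations, length >= 3.
#' @return Named list, one element per model, each a list with
#'   \code{params}, \code{loglik}, \code{n_params}, \code{cdf} (fitted
#'   distribution function) and \code{converged}.
#' @export
fit_competitors <- function(data) {
  if (length(data) < 3L || any(!is.finite(data)) || any(data <= 0)) {
    stop("'data' must be at least 3 positive finite values", call. = FALSE)
  }
  x <- as.numeric(data)
  n <- length(x)
  out <- list()

  sm <- prog_sample(sort(x), prog_scheme("custom", n, n,
                                         removals = integer(0)))
  fit <- fit_loglogis(sm)
  out$loglogistic <- list(
    params = c(alpha = fit$alpha, beta = fit$beta),
    loglik = fit$loglik, n_params = 2L,
    cdf = local({
      a <- fit$alpha; b <- fit$beta
      function(q) ploglogis(q, a, b)
    }),
    converged = fit$converged)

  wb <- stats::optim(
    c(log(1), log(mean(x))),
    function(p) {
      nll <- suppressWarnings(
        -sum(stats::dweibull(x, exp(p[1]), exp(p[2]), log = TRUE)))
      if (is.finite(nll)) nll else 1e10
    },
    method = "BFGS", control = list(reltol = 1e-12))
  out$weibull <- list(
    params = c(shape = exp(wb$par[1]), scale = exp(wb$par[2])),
    loglik = -wb$value, n_params = 2L,
    cdf = local({
      sh <- exp(wb$par[1]); sc <- exp(wb$par[2])
      function(q) stats::pweibull(q, sh, sc)
    }),
    converged = wb$convergence == 0L)

  mu <- mean(log(x))
  sg <- sqrt(mean((log(x) - mu)^2))    # MLE uses divisor n
  out$lognormal <- list(
    params = c(meanlog = mu, sdlog = sg),
    loglik = sum(stats::dlnorm(x, mu, sg, log = TRUE)),
    n_params = 2L,
    cdf = function(q) stats::plnorm(q, mu, sg),
    converged = TRUE)

  rate <- 1 / mean(x)
  out$exponential <- list(
    params = c(rate = rate),
    loglik = sum(stats::dexp(x, rate, log = TRUE)),
    n_params = 1L,
    cdf = function(q) stats::pexp(q, rate),
    converged = TRUE)

  out
}

#' Akaike and Bayesian information criteria
#'
#' \code{AIC = -2*loglik + 2*n_params};
#' \code{BIC = -2*loglik + n_params*log(n)}.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n sample size.
#' @return Named vector \code{c(aic=, bic=)}.
#' @export
info_criteria <- function(loglik, n_params, n) {
  if (n < 1) stop("'n' must be positive", call. = FALSE)
  c(aic = -2 * loglik + 2 * n_params,
    bic = -2 * loglik + n_params * log(n))
}

#' EDF goodness-of-fit statistics
#'
#' Computes the classical empirical-distribution-function statistics of a
#' complete sample against a fitted continuous CDF, on the transformed
#' values \eqn{u_{(i)} = F(x_{(i)})}:
#' Kolmogorov-Smirnov \eqn{\max(D^+, D^-)} with
#' \eqn{D^+ = \max_i\{i/n - u_{(i)}\}},
#' \eqn{D^- = \max_i\{u_{(i)} - (i-1)/n\}};
#' Kuiper \eqn{D^+ + D^-};
#' Cramer-von Mises \eqn{W^2 = 1/(12n) + \sum_i (u_{(i)} - (2i-1)/(2n))^2};
#' Watson \eqn{U^2 = W^2 - n(\bar u - 1/2)^2};
#' Anderson-Darling \eqn{A^2 = -n - n^{-1}\sum_i (2i-1)
#'   [\log u_{(i)} + \log(1 - u_{(n+1-i)})]}.
#'
#' Statistics only — with estimated parameters the null distributions are
#' nonstandard, so no p-values are attached.
#'
#' @param data complete positive sample.
#' @param cdf fitted distribution function.
#' @return Named vector \code{c(ks, cvm, ad, kuiper, watson)}.
#' @export
gof_statistics <- function(data, cdf) {
  u <- cdf(sort(as.numeric(data)))
  n <- length(u)
  if (any(u <= 0) || any(u >= 1)) {
    stop("fitted CDF degenerates to 0 or 1 at a data point", call. = FALSE)
  }
  i <- seq_len(n)
  d_plus <- max(i / n - u)
  d_minus <- max(u - (i - 1) / n)
  cvm <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
  ad <- -n - sum((2 * i - 1) * (log(u) + log(1 - rev(u)))) / n
  c(ks = max(d_plus, d_minus),
    cvm = cvm,
    ad = ad,
    kuiper = d_plus + d_minus,
    watson = cvm - n * (mean(u) - 0.5)^2)
}

#' Model-screening table for a complete dataset
#'
#' Fits the four candidate lifetime models and assembles log-likelihood,
#' AIC, BIC and the five EDF statistics into one table, one row per
#' model.
#'
#' @param data complete positive sample.
#' @return Data frame with columns \code{model}, \code{loglik},
#'   \code{aic}, \code{bic}, \code{ks}, \code{cvm}, \code{ad},
#'   \code{kuiper}, \code{watson}.
#' @examples
#' model_table(ll_data("bladder")$values)
#' @export
model_table <- function(data) {
  fits <- fit_competitors(data)
  n <- length(data)
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    ic <- info_criteria(f$loglik, f$n_params, n)
    gof <- gof_statistics(data, f$cdf)
    data.frame(model = nm, loglik = f$loglik,
               aic = ic[["aic"]], bic = ic[["bic"]],
               ks = gof[["ks"]], cvm = gof[["cvm"]], ad = gof[["ad"]],
               kuiper = gof[["kuiper"]], watson = gof[["watson"]])
  }))
}
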