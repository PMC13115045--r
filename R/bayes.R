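#' Prior specifications for (alpha, beta)
#'
#' Two priors are supported:
#' \describe{
#'   \item{\code{jeffreys}}{the improper prior \eqn{\pi(\alpha,\beta)
#'     \propto (\alpha\beta)^{-1}}, which is flat in the log-parameters
#'     after the Jacobian.  For numerical stability it is truncated to
#'     \code{alpha > 1e-4} and \code{beta > 1.05}.}
#'   \item{\code{empirical}}{independent Gamma priors with shape 30 and
#'     rate calibrated so the prior mean equals the MLE of the sample at
#'     hand: \eqn{\alpha \sim \Gamma(30, 30/\hat\alpha)},
#'     \eqn{\beta \sim \Gamma(30, 30/\hat\beta)} (prior CV
#'     \eqn{1/\sqrt{30} \approx 18\%}).}
#'   \item{\code{gamma}}{independent Gamma priors with user-supplied
#'     shape/rate hyperparameters.}
#' }
#'
#' @param kind \code{"jeffreys"}, \code{"empirical"} or \code{"gamma"}.
#' @param fit converged \code{llfit}, required for \code{"empirical"}.
#' @param a_alpha,b_alpha,a_beta,b_beta Gamma shape/rate pairs for
#'   \code{kind = "gamma"}.
#' @return Object of class \code{"ll_prior"}.
#' @export
ll_prior <- function(kind = c("jeffreys", "empirical", "gamma"),
                     fit = NULL,
                     a_alpha = NULL, b_alpha = NULL,
                     a_beta = NULL, b_beta = NULL) {
  kind <- match.arg(kind)
  out <- list(kind = kind)
  if (kind == "jeffreys") {
    out$trunc_alpha_min <- 1e-4
    out$trunc_beta_min <- 1.05
  } else if (kind == "empirical") {
    if (is.null(fit) || !inherits(fit, "llfit") || !fit$converged) {
      stop("empirical prior requires a converged 'llfit'", call. = FALSE)
    }
    out$a_alpha <- 30
    out$b_alpha <- 30 / fit$alpha
    out$a_beta <- 30
    out$b_beta <- 30 / fit$beta
    out$kind <- "gamma"
  } else {
    hp <- c(a_alpha, b_alpha, a_beta, b_beta)
    if (length(hp) != 4L || any(!is.finite(hp)) || any(hp <= 0)) {
      stop("gamma prior needs four positive hyperparameters", call. = FALSE)
    }
    out$a_alpha <- a_alpha
    out$b_alpha <- b_alpha
    out$a_beta <- a_beta
    out$b_beta <- b_beta
  }
  structure(out, class = "ll_prior")
}

#' Log posterior kernel in log-parameter space
#'
#' Joint log target for the Metropolis-Hastings-within-Gibbs sampler,
#' expressed in \eqn{(\eta, \zeta) = (\log\alpha, \log\beta)}: the censored
#' log-likelihood plus log prior plus the change-of-variables Jacobian
#' \eqn{\eta + \zeta}.  The two full conditional kernels are this function
#' with the other coordinate held fixed, so acceptance ratios for both
#' blocks are formed from the same evaluation.  Under the truncated
#' Jeffreys prior the kernel reduces to the log-likelihood in
#' \eqn{(\eta,\zeta)} (flat after Jacobian); outside the truncation region
#' \code{-Inf} is returned.
#'
#' @param eta,zeta log-scale parameters.
#' @param sample a \code{prog_sample}.
#' @param prior an \code{ll_prior}.
#' @return Scalar log kernel (up to an additive constant).
#' @export
log_post_kernel <- function(eta, zeta, sample, prior) {
  stopifnot(inherits(prior, "ll_prior"))
  alpha <- exp(eta)
  beta <- exp(zeta)
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    return(-Inf)
  }
  if (prior$kind == "jeffreys") {
    if (alpha <= prior$trunc_alpha_min || beta <= prior$trunc_beta_min) {
      return(-Inf)
    }
    # log prior -eta - zeta cancels the Jacobian eta + zeta
    return(loglik_prog(alpha, beta, sample))
  }
  loglik_prog(alpha, beta, sample) +
    (prior$a_alpha - 1) * eta - prior$b_alpha * alpha +
    (prior$a_beta - 1) * zeta - prior$b_beta * beta +
    eta + zeta
}

#' Metropolis-Hastings-within-Gibbs posterior sampler
#'
#' Samples the joint posterior of \eqn{(\alpha, \beta)} by sequential
#' Gaussian random-walk updates of \eqn{\eta = \log\alpha} then
#' \eqn{\zeta = \log\beta}, each accepted by a Metropolis-Hastings ratio of
#' the log-space kernels.  Draws are back-transformed, burn-in discarded
#' and the remainder thinned, retaining \code{M = (n_iter - burn_in)/thin}
#' pairs.
#'
#' During burn-in only, the proposal standard deviations are adapted every
#' 100 iterations: multiplied by 1.1 when the windowed acceptance rate
#' exceeds 0.50, divided by 1.1 when it falls below 0.20.  Adaptation is
#' frozen after burn-in so the retained chain targets the exact posterior.
#'
#' @param sample a \code{prog_sample}.
#' @param prior an \code{ll_prior}.
#' @param init initial \code{c(alpha, beta)}; defaults to the MLE of
#'   \code{sample}.
#' @param n_iter total iterations N (default 10000).
#' @param burn_in burn-in B (default 2000).
#' @param thin thinning interval h (default 10).
#' @param prop_sd optional initial proposal standard deviations
#'   \code{c(s_eta, s_zeta)}; defaults to the delta-method log-scale
#'   standard errors from the observed information of the MLE fit.
#' @param adapt adapt proposal sds during burn-in (default TRUE).
#' @return Object of class \code{"ll_posterior"}: list with vectors
#'   \code{alpha}, \code{beta} (length M), acceptance rates, proposal sds,
#'   configuration, and the pre-thinning log-scale chains \code{eta_chain},
#'   \code{zeta_chain} for diagnostics.
#' @examples
#' sc <- prog_scheme("early", 30, 20)
#' set.seed(7)
#' sm <- rprogressive(3, 5, sc)
#' post <- mh_gibbs(sm, ll_prior("jeffreys"), n_iter = 1000, burn_in = 200)
#' mean(post$alpha)
#' @export
mh_gibbs <- function(sample, prior, init = NULL,
                     n_iter = 10000L, burn_in = 2000L, thin = 10L,
                     prop_sd = NULL, adapt = TRUE) {
  stopifnot(inherits(sample, "prog_sample"), inherits(prior, "ll_prior"))
  if (burn_in >= n_iter) stop("burn_in must be < n_iter", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  fit <- NULL
  if (is.null(init) || is.null(prop_sd)) {
    fit <- fit_loglogis(sample)
  }
  if (is.null(init)) init <- c(fit$alpha, fit$beta)
  check_ll_params(init[1], init[2])
  if (is.null(prop_sd)) {
    v <- diag(fit$vcov)
    if (any(!is.finite(v)) || any(v <= 0)) {
      prop_sd <- c(0.1, 0.1)
    } else {
      # map observed-information sds to log scale by the delta method
      prop_sd <- sqrt(v) / c(fit$alpha, fit$beta)
    }
  }
  eta <- log(init[1])
  zeta <- log(init[2])
  lp <- log_post_kernel(eta, zeta, sample, prior)
  if (!is.finite(lp)) {
    stop("posterior kernel is not finite at the initial state", call. = FALSE)
  }
  s_eta <- prop_sd[1]
  s_zeta <- prop_sd[2]
  eta_chain <- numeric(n_iter)
  zeta_chain <- numeric(n_iter)
  acc_eta <- 0L
  acc_zeta <- 0L
  win_eta <- 0L
  win_zeta <- 0L
  for (l in seq_len(n_iter)) {
    # eta block
    eta_star <- eta + stats::rnorm(1L, 0, s_eta)
    lp_star <- log_post_kernel(eta_star, zeta, sample, prior)
    if (is.finite(lp_star) && log(stats::runif(1L)) <= lp_star - lp) {
      eta <- eta_star
      lp <- lp_star
      if (l > burn_in) acc_eta <- acc_eta + 1L else win_eta <- win_eta + 1L
    }
    # zeta block
    zeta_star <- zeta + stats::rnorm(1L, 0, s_zeta)
    lp_star <- log_post_kernel(eta, zeta_star, sample, prior)
    if (is.finite(lp_star) && log(stats::runif(1L)) <= lp_star - lp) {
      zeta <- zeta_star
      lp <- lp_star
      if (l > burn_in) acc_zeta <- acc_zeta + 1L else win_zeta <- win_zeta + 1L
    }
    eta_chain[l] <- eta
    zeta_chain[l] <- zeta
    if (adapt && l <= burn_in && l %% 100L == 0L) {
      if (s_eta > 0) {
        rate <- win_eta / 100
        if (rate > 0.50) s_eta <- s_eta * 1.1
        if (rate < 0.20) s_eta <- s_eta / 1.1
      }
      if (s_zeta > 0) {
        rate <- win_zeta / 100
        if (rate > 0.50) s_zeta <- s_zeta * 1.1
        if (rate < 0.20) s_zeta <- s_zeta / 1.1
      }
      win_eta <- 0L
      win_zeta <- 0L
    }
  }
  keep <- seq.int(burn_in + thin, n_iter, by = thin)
  m <- length(keep)
  if (m < 100L) {
    warning(sprintf("only %d retained draws; consider more iterations", m))
  }
  n_post <- n_iter - burn_in
  structure(list(alpha = exp(eta_chain[keep]), beta = exp(zeta_chain[keep]),
                 accept_rate_eta = acc_eta / n_post,
                 accept_rate_zeta = acc_zeta / n_post,
                 prop_sd = c(eta = s_eta, zeta = s_zeta),
                 config = list(n_iter = n_iter, burn_in = burn_in,
                               thin = thin, M = m),
                 eta_chain = eta_chain, zeta_chain = zeta_chain),
            class = "ll_posterior")
}

#' @export
print.ll_posterior <- function(x, ...) {
  cat(sprintf("Posterior draws: M = %d (N = %d, burn-in = %d, thin = %d)\n",
              x$config$M, x$config$n_iter, x$config$burn_in, x$config$thin))
  cat(sprintf("  alpha: mean %.4f;  beta: mean %.4f\n",
              mean(x$alpha), mean(x$beta)))
  cat(sprintf("  acceptance rates: eta %.1f%%, zeta %.1f%%\n",
              100 * x$accept_rate_eta, 100 * x$accept_rate_zeta))
  invisible(x)
}

#' Posterior point estimate and equal-tailed credible interval
#'
#' The squared-error-loss Bayes estimate of \code{g(alpha, beta)} is the
#' draw average; the \code{100(1-xi)\%} equal-tailed credible interval is
#' read off the sorted draws at order-statistic indices
#' \code{floor(M*xi/2)} and \code{floor(M*(1-xi/2))} (lower index clamped
#' to 1).
#'
#' @param posterior an \code{ll_posterior}.
#' @param g function of \code{(alpha, beta)} applied elementwise to the
#'   draws; defaults to extracting \code{alpha}.
#' @param xi credible-tail mass (default 0.05 for a 95\% interval).
#' @return List with \code{estimate} and \code{interval} (length-2 vector).
#' @export
posterior_summary <- function(posterior, g = function(a, b) a, xi = 0.05) {
  stopifnot(inherits(posterior, "ll_posterior"))
  th <- g(posterior$alpha, posterior$beta)
  m <- length(th)
  if (m < 2L) stop("need at least two draws", call. = FALSE)
  s <- sort(th)
  lo <- max(1L, floor(m * xi / 2))
  hi <- min(m, floor(m * (1 - xi / 2)))
  list(estimate = mean(th), interval = c(s[lo], s[hi]))
}

#' Chain diagnostics
#'
#' Lag-k autocorrelations (to \code{lag_max}) of the retained draws and the
#' pre-thinning trace series, for external plotting.
#'
#' @param posterior an \code{ll_posterior}.
#' @param lag_max maximum lag (default 50).
#' @return List with \code{acf_alpha}, \code{acf_beta} and the two full
#'   log-scale chains.
#' @export
posterior_diagnostics <- function(posterior, lag_max = 50L) {
  stopifnot(inherits(posterior, "ll_posterior"))
  list(
    acf_alpha = stats::acf(posterior$alpha, lag.max = lag_max,
                           plot = FALSE)$acf[, 1, 1],
    acf_beta = stats::acf(posterior$beta, lag.max = lag_max,
                          plot = FALSE)$acf[, 1, 1],
    eta_chain = posterior$eta_chain,
    zeta_chain = posterior$zeta_chain)
}
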