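#' Log-Logistic (Fisk) distribution
#'
#' Density, distribution function, survival function, hazard, quantile
#' function, raw moments and random generation for the two-parameter
#' Log-Logistic distribution with scale \code{alpha} and shape \code{beta}:
#' \deqn{F(t) = \frac{1}{1 + (t/\alpha)^{-\beta}}, \quad t > 0.}
#'
#' All kernels are evaluated through the log-space intermediate
#' \eqn{z = \beta(\log t - \log\alpha)}, for which \eqn{F(t)} is the standard
#' logistic function of \eqn{z}; this avoids overflow for extreme
#' \eqn{t/\alpha} ratios.
#'
#' @param t,q vector of positive times.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param alpha scale parameter (> 0), in time units.
#' @param beta shape parameter (> 0), dimensionless.  The r-th raw moment
#'   exists if and only if \code{beta > r}; the hazard is unimodal
#'   (upside-down bathtub) for \code{beta > 1} and decreasing otherwise.
#' @param log,log.p logical; return log values / accept log probabilities.
#'
#' @return Numeric vector.  \code{rloglogis} returns \code{n} iid draws
#'   generated by inverse-transform sampling.
#' @name loglogis
NULL

check_ll_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) ||
      length(alpha) != 1L || length(beta) != 1L ||
      !is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("'alpha' and 'beta' must be single positive finite numbers",
         call. = FALSE)
  }
  invisible(list(alpha = alpha, beta = beta))
}

check_positive_t <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop("'t' must be positive and finite", call. = FALSE)
  }
  invisible(t)
}

#' @rdname loglogis
#' @export
dloglogis <- function(t, alpha, beta, log = FALSE) {
  check_ll_params(alpha, beta)
  check_positive_t(t)
  z <- beta * (base::log(t) - base::log(alpha))
  out <- base::log(beta) - base::log(t) +
    stats::plogis(z, log.p = TRUE) + stats::plogis(-z, log.p = TRUE)
  if (log) out else exp(out)
}

#' @rdname loglogis
#' @export
ploglogis <- function(q, alpha, beta, log.p = FALSE) {
  check_ll_params(alpha, beta)
  check_positive_t(q)
  z <- beta * (base::log(q) - base::log(alpha))
  stats::plogis(z, log.p = log.p)
}

#' @rdname loglogis
#' @export
sloglogis <- function(q, alpha, beta, log.p = FALSE) {
  check_ll_params(alpha, beta)
  check_positive_t(q)
  z <- beta * (base::log(q) - base::log(alpha))
  stats::plogis(-z, log.p = log.p)
}

#' @rdname loglogis
#' @export
hloglogis <- function(t, alpha, beta) {
  check_ll_params(alpha, beta)
  check_positive_t(t)
  z <- beta * (base::log(t) - base::log(alpha))
  beta / t * stats::plogis(z)
}

#' @rdname loglogis
#' @export
qloglogis <- function(p, alpha, beta) {
  check_ll_params(alpha, beta)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  }
  alpha * exp(stats::qlogis(p) / beta)
}

#' @rdname loglogis
#' @param r order of the raw moment (positive integer); requires
#'   \code{beta > r}.
#' @details The r-th raw moment, when it exists, is
#'   \eqn{\alpha^r (r\pi/\beta) / \sin(r\pi/\beta)}.
#' @export
loglogis_moment <- function(alpha, beta, r = 1L) {
  check_ll_params(alpha, beta)
  if (length(r) != 1L || r < 1 || r != round(r)) {
    stop("'r' must be a positive integer", call. = FALSE)
  }
  if (beta <= r) {
    stop(sprintf(
      "moment of order %d does not exist: requires beta > %d (beta = %g)",
      r, r, beta), call. = FALSE)
  }
  u <- r * pi / beta
  alpha^r * u / sin(u)
}

#' @rdname loglogis
#' @export
rloglogis <- function(n, alpha, beta) {
  check_ll_params(alpha, beta)
  qloglogis(stats::runif(n), alpha, beta)
}
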