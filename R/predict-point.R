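#' Prediction target: a future order statistic of withdrawn units
#'
#' Identifies \eqn{Y = Y_{k:r_j}}, the k-th failure among the \eqn{r_j}
#' units withdrawn at censoring stage j.  By the Markov property of
#' progressively censored order statistics, given the observed sample the
#' law of Y is that of the k-th order statistic of \eqn{r_j} draws from the
#' parent distribution left-truncated at the stage-j failure time
#' \eqn{x_j}.
#'
#' @param sample a \code{prog_sample}.
#' @param stage_j censoring stage (1..m) with at least one removal.
#' @param rank_k order of the future failure among the withdrawn units
#'   (1..r_j).
#' @return Object of class \code{"pred_target"}: list with \code{stage_j},
#'   \code{rank_k}, \code{r_j}, \code{x_j}.
#' @export
pred_target <- function(sample, stage_j, rank_k) {
  stopifnot(inherits(sample, "prog_sample"))
  m <- sample$scheme$m
  if (stage_j < 1 || stage_j > m) stop("stage_j out of range", call. = FALSE)
  r_j <- sample$scheme$removals[stage_j]
  if (r_j < 1) stop("no units withdrawn at this stage", call. = FALSE)
  if (rank_k < 1 || rank_k > r_j) {
    stop(sprintf("rank_k must lie in 1..r_j = %d", r_j), call. = FALSE)
  }
  structure(list(stage_j = as.integer(stage_j), rank_k = as.integer(rank_k),
                 r_j = as.integer(r_j), x_j = sample$times[stage_j]),
            class = "pred_target")
}

# survival ratio rho(y) = S(y)/S(x_j) in (0, 1], computed in log space
cond_log_rho <- function(y, target, alpha, beta) {
  sloglogis(y, alpha, beta, log.p = TRUE) -
    sloglogis(target$x_j, alpha, beta, log.p = TRUE)
}

#' Conditional density of the future order statistic
#'
#' Density of \eqn{Y_{k:r_j}} given the observed sample, the alternating
#' binomial sum over the truncated parent law:
#' \deqn{f_{Y|x}(y) = C_{k,r_j} \sum_{v=0}^{k-1} W_v\,
#'   \rho(y)^{r_j - v}\, h(y)}
#' with \eqn{\rho(y) = S(y)/S(x_j)}, \eqn{h} the parent hazard,
#' \eqn{W_v = \binom{k-1}{v}(-1)^{k-1-v}} and \eqn{C_{k,r_j} =
#' r_j!/\{(k-1)!(r_j-k)!\}}.  Returns 0 for \code{y <= x_j} by convention.
#'
#' The alternating sum collapses analytically to the Beta-type form
#' \eqn{C_{k,r_j}\,\rho^{r_j-k+1}(1-\rho)^{k-1} h(y)}; the implementation
#' evaluates this collapsed form in log space, because direct summation
#' loses all precision near \eqn{y \approx x_j} once \eqn{k} exceeds about
#' 15 (binomial weights up to \eqn{\binom{k-1}{\lfloor k/2\rfloor}}
#' amplify rounding noise above the vanishing true value).  The direct
#' summation is retained in the test suite as the independent oracle at
#' moderate \eqn{k}.
#'
#' @param y evaluation points.
#' @param target a \code{pred_target}.
#' @param alpha,beta Log-Logistic parameters.
#' @return Vector of density values.
#' @export
cond_pdf <- function(y, target, alpha, beta) {
  stopifnot(inherits(target, "pred_target"))
  check_ll_params(alpha, beta)
  out <- numeric(length(y))
  ok <- y > target$x_j
  if (any(ok)) {
    out[ok] <- exp(cond_log_pdf_stable(y[ok], target, alpha, beta))
  }
  out
}

# stable log conditional density via the collapsed Beta form
cond_log_pdf_stable <- function(y, target, alpha, beta) {
  k <- target$rank_k
  r <- target$r_j
  lrho <- cond_log_rho(y, target, alpha, beta)
  l1m <- log1p(-exp(lrho))          # log(1 - rho); rho < 1 for y > x_j
  l1m[lrho == 0] <- -Inf
  lgamma(r + 1) - lgamma(k) - lgamma(r - k + 1) +
    (r - k + 1) * lrho + (if (k > 1) (k - 1) * l1m else 0) +
    log(hloglogis(y, alpha, beta))
}

#' Conditional survival function of the future order statistic
#'
#' \deqn{S_{Y|x}(y) = C_{k,r_j} \sum_{v=0}^{k-1} \frac{W_v}{r_j - v}
#'   \rho(y)^{r_j - v},} equal to 1 at \eqn{y = x_j} and strictly
#' decreasing to 0.  The sum is the regularized incomplete beta function
#' \eqn{I_{\rho}(r_j - k + 1, k)} of the probability-integral-transform
#' representation, and is evaluated through \code{pbeta} for the same
#' stability reason as [cond_pdf()]; the alternating sum serves as the
#' test-suite oracle at moderate \eqn{k}.
#'
#' @inheritParams cond_pdf
#' @return Vector of survival probabilities in [0, 1].
#' @export
cond_sf <- function(y, target, alpha, beta) {
  stopifnot(inherits(target, "pred_target"))
  check_ll_params(alpha, beta)
  k <- target$rank_k
  r <- target$r_j
  rho <- exp(cond_log_rho(pmax(y, target$x_j), target, alpha, beta))
  stats::pbeta(rho, r - k + 1, k)
}

#' Median of the Beta law of the probability-integral transform
#'
#' The truncated-CDF transform of the future order statistic satisfies
#' \eqn{U = G(Y) \sim \mathrm{Beta}(k, r - k + 1)}; its median
#' \eqn{m_{k,r}} solves \eqn{I_{m}(k, r-k+1) = 1/2}.
#'
#' @param k order of the future failure.
#' @param r number of withdrawn units, \code{k <= r}.
#' @return Median of Beta(k, r - k + 1) in (0, 1).
#' @export
beta_median <- function(k, r) {
  if (k < 1 || r < k) stop("need 1 <= k <= r", call. = FALSE)
  stats::qbeta(0.5, k, r - k + 1)
}

#' Conditional mean and variance of the future order statistic
#'
#' Moments of the conditional law of \eqn{Y_{k:r_j}}, computed by adaptive
#' quadrature over the unit interval after the substitution
#' \eqn{t = (y - x_j)/(1 + y - x_j)}.  The s-th conditional moment is
#' finite only when \eqn{\beta (r_j - k + 1) > s} (the tail exponent of
#' the conditional density); violations raise an error.
#'
#' @param target a \code{pred_target}.
#' @param alpha,beta Log-Logistic parameters.
#' @param want_variance also compute the second moment (default TRUE).
#' @param rel_tol quadrature relative tolerance (default 1e-9).
#' @return List with \code{mean} and (if requested) \code{variance},
#'   plus \code{abs_error} quadrature error estimates.
#' @export
cond_moments <- function(target, alpha, beta, want_variance = TRUE,
                         rel_tol = 1e-9) {
  stopifnot(inherits(target, "pred_target"))
  check_ll_params(alpha, beta)
  k <- target$rank_k
  r <- target$r_j
  tail_exp <- beta * (r - k + 1)
  if (tail_exp <= 1) {
    stop(sprintf(
      "conditional mean diverges: beta*(r_j - k + 1) = %.3f <= 1", tail_exp),
      call. = FALSE)
  }
  if (want_variance && tail_exp <= 2) {
    stop(sprintf(
      "conditional variance diverges: beta*(r_j - k + 1) = %.3f <= 2",
      tail_exp), call. = FALSE)
  }
  xj <- target$x_j
  integrand <- function(t, pow) {
    y <- xj + t / (1 - t)
    exp(pow * log(y) + cond_log_pdf_stable(y, target, alpha, beta) -
          2 * log1p(-t))
  }
  q1 <- stats::integrate(integrand, 0, 1, pow = 1,
                         rel.tol = rel_tol, abs.tol = rel_tol,
                         subdivisions = 400L)
  out <- list(mean = q1$value, abs_error = q1$abs.error)
  if (want_variance) {
    q2 <- stats::integrate(integrand, 0, 1, pow = 2,
                           rel.tol = rel_tol, abs.tol = rel_tol,
                           subdivisions = 400L)
    out$variance <- max(0, q2$value - q1$value^2)
    out$abs_error <- c(out$abs_error, q2$abs.error)
  }
  out
}

#' Best Unbiased Predictor (plug-in conditional mean)
#'
#' \eqn{\hat Y_{BUP} = E[Y \mid x, \hat\alpha, \hat\beta]} at the MLE,
#' with a first-order delta-method variance
#' \eqn{\nabla T^\top J_n^{-1} \nabla T} attached, where the gradient of
#' the conditional-mean map \eqn{T(\phi)} is obtained by central finite
#' differences with step \code{1e-4 * (1 + |parameter|)}.
#'
#' @param target a \code{pred_target}.
#' @param fit converged \code{llfit}.
#' @return Object of class \code{"ll_prediction"}: list with \code{value},
#'   \code{method = "BUP"}, \code{variance} (delta-method),
#'   \code{conditional_variance}, \code{diagnostics}.
#' @export
predict_bup <- function(target, fit) {
  stopifnot(inherits(target, "pred_target"), inherits(fit, "llfit"))
  mom <- cond_moments(target, fit$alpha, fit$beta)
  tfun <- function(a, b) {
    cond_moments(target, a, b, want_variance = FALSE)$mean
  }
  ha <- 1e-4 * (1 + abs(fit$alpha))
  hb <- 1e-4 * (1 + abs(fit$beta))
  grad <- c((tfun(fit$alpha + ha, fit$beta) -
               tfun(fit$alpha - ha, fit$beta)) / (2 * ha),
            (tfun(fit$alpha, fit$beta + hb) -
               tfun(fit$alpha, fit$beta - hb)) / (2 * hb))
  dvar <- drop(t(grad) %*% fit$vcov %*% grad)
  structure(list(value = mom$mean, method = "BUP",
                 variance = dvar,
                 conditional_variance = mom$variance,
                 diagnostics = list(quad_abs_error = mom$abs_error,
                                    grad = grad)),
            class = "ll_prediction")
}

#' Conditional Median Predictor (closed form)
#'
#' Median of the conditional law of the future order statistic, in closed
#' form through the Beta median \eqn{m_{k,r_j}}:
#' \deqn{\hat Y_{CMP} = \hat\alpha \Big[\frac{m_{k,r_j} +
#'   (x_j/\hat\alpha)^{\hat\beta}}{1 - m_{k,r_j}}\Big]^{1/\hat\beta}.}
#' Always finite; no moment condition is required, which makes the CMP the
#' predictor of choice in heavy-tailed regimes (\eqn{\beta \le 2}).
#'
#' @inheritParams predict_bup
#' @return An \code{ll_prediction} with \code{method = "CMP"}.
#' @export
predict_cmp <- function(target, fit) {
  stopifnot(inherits(target, "pred_target"), inherits(fit, "llfit"))
  m_kr <- beta_median(target$rank_k, target$r_j)
  a <- fit$alpha
  b <- fit$beta
  val <- a * ((m_kr + (target$x_j / a)^b) / (1 - m_kr))^(1 / b)
  structure(list(value = val, method = "CMP", variance = NULL,
                 diagnostics = list(beta_median = m_kr)),
            class = "ll_prediction")
}

#' Bayesian Predictor (posterior-predictive mean)
#'
#' \eqn{\hat Y_{BP} = M^{-1}\sum_{l'} E[Y \mid x, \alpha^{(l')},
#' \beta^{(l')}]}, the conditional mean averaged over retained posterior
#' draws, with the posterior-predictive variance decomposed by the law of
#' total variance into the mean conditional variance plus the between-draw
#' variance of the conditional means.
#'
#' Draws violating the moment-existence condition are skipped and counted;
#' more than 1\% violators is an error.
#'
#' @param target a \code{pred_target}.
#' @param posterior an \code{ll_posterior}.
#' @return An \code{ll_prediction} with \code{method = "BP"},
#'   \code{variance} (posterior-predictive, when second moments exist) and
#'   \code{diagnostics$n_violations}.
#' @export
predict_bp <- function(target, posterior) {
  stopifnot(inherits(target, "pred_target"),
            inherits(posterior, "ll_posterior"))
  m <- length(posterior$alpha)
  k <- target$rank_k
  r <- target$r_j
  tail_exp <- posterior$beta * (r - k + 1)
  ok <- tail_exp > 1
  n_viol <- sum(!ok)
  if (n_viol > 0.01 * m) {
    stop(sprintf(
      "conditional mean undefined for %d of %d posterior draws", n_viol, m),
      call. = FALSE)
  }
  want_var <- all(tail_exp[ok] > 2)
  mu <- numeric(sum(ok))
  sig2 <- if (want_var) numeric(sum(ok)) else NULL
  ia <- posterior$alpha[ok]
  ib <- posterior$beta[ok]
  for (i in seq_along(ia)) {
    mom <- cond_moments(target, ia[i], ib[i], want_variance = want_var,
                        rel_tol = 1e-8)
    mu[i] <- mom$mean
    if (want_var) sig2[i] <- mom$variance
  }
  val <- mean(mu)
  pv <- if (want_var) mean(sig2) + stats::var(mu) else NULL
  structure(list(value = val, method = "BP", variance = pv,
                 diagnostics = list(n_violations = n_viol,
                                    n_draws = m,
                                    between_var = stats::var(mu))),
            class = "ll_prediction")
}

#' @export
print.ll_prediction <- function(x, ...) {
  cat(sprintf("%s point prediction: %.4f", x$method, x$value))
  if (!is.null(x$variance)) cat(sprintf("  (variance %.4g)", x$variance))
  cat("\n")
  invisible(x)
}
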