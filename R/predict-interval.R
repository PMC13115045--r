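# bracketed root-finding on a decreasing survival-type curve:
# solve s(y) = p for y > x_j.  Doubles the upper endpoint from
# x_j + step until bracketed (at most 60 doublings), then Brent refinement.
solve_survival <- function(sfun, p, x_j, step) {
  lo <- x_j
  hi <- x_j + step
  n_doublings <- 0L
  while (sfun(hi) > p) {
    lo <- hi
    hi <- x_j + (hi - x_j) * 2
    n_doublings <- n_doublings + 1L
    if (n_doublings > 60L) {
      stop(sprintf(
        "failed to bracket survival level %g after 60 doublings", p),
        call. = FALSE)
    }
  }
  stats::uniroot(function(y) sfun(y) - p, lower = lo, upper = hi,
                 tol = 1e-10 * max(1, hi))$root
}

new_interval <- function(lower, upper, method, level, n_draws = NULL) {
  structure(list(lower = lower, upper = upper, method = method,
                 level = level, n_predictive_draws = n_draws),
            class = "ll_interval")
}

#' @export
print.ll_interval <- function(x, ...) {
  cat(sprintf("%s %.0f%% prediction interval: (%.4f, %.4f)\n",
              x$method, 100 * x$level, x$lower, x$upper))
  invisible(x)
}

#' Pivotal (frequentist plug-in) prediction interval
#'
#' Equal-tailed interval whose endpoints solve the plug-in conditional
#' survival function at the MLE:
#' \eqn{S_{Y|x}(L \mid \hat\alpha,\hat\beta) = 1 - \gamma/2} and
#' \eqn{S_{Y|x}(U \mid \hat\alpha,\hat\beta) = \gamma/2}.  The survival
#' curve is strictly decreasing on \eqn{(x_j, \infty)}, so both roots are
#' unique; they are found by geometric bracket expansion followed by Brent
#' refinement.
#'
#' @param target a \code{pred_target}.
#' @param fit converged \code{llfit}.
#' @param level nominal coverage \code{1 - gamma} (default 0.95).
#' @return An \code{ll_interval} with \code{method = "PPI"}.
#' @export
predict_ppi <- function(target, fit, level = 0.95) {
  stopifnot(inherits(target, "pred_target"), inherits(fit, "llfit"))
  gamma <- 1 - level
  sfun <- function(y) cond_sf(y, target, fit$alpha, fit$beta)
  lower <- solve_survival(sfun, 1 - gamma / 2, target$x_j, fit$alpha)
  upper <- solve_survival(sfun, gamma / 2, target$x_j, fit$alpha)
  new_interval(lower, upper, "PPI", level)
}

#' Bayesian equal-tailed prediction interval
#'
#' Endpoints solve the posterior-predictive survival curve — the average
#' of the per-draw conditional survival functions over the retained MCMC
#' draws — at \eqn{1-\gamma/2} and \eqn{\gamma/2}.  The average of
#' monotone decreasing curves is monotone decreasing, so the same
#' bracketed root-finder applies.
#'
#' @param target a \code{pred_target}.
#' @param posterior an \code{ll_posterior} with at least 100 retained
#'   draws.
#' @param level nominal coverage (default 0.95).
#' @return An \code{ll_interval} with \code{method = "ETI"}.
#' @export
predict_eti <- function(target, posterior, level = 0.95) {
  stopifnot(inherits(target, "pred_target"),
            inherits(posterior, "ll_posterior"))
  m <- length(posterior$alpha)
  if (m < 100L) stop("need at least 100 posterior draws", call. = FALSE)
  gamma <- 1 - level
  k <- target$rank_k
  r <- target$r_j
  # per-draw survival via the Beta representation (equals the alternating
  # sum of cond_sf exactly; cheaper when averaged over many draws)
  sfun <- function(y) {
    lr <- vapply(seq_len(m), function(i) {
      cond_log_rho(y, target, posterior$alpha[i], posterior$beta[i])
    }, numeric(1))
    mean(stats::pbeta(exp(lr), r - k + 1, k))
  }
  step <- mean(posterior$alpha)
  lower <- solve_survival(sfun, 1 - gamma / 2, target$x_j, step)
  upper <- solve_survival(sfun, gamma / 2, target$x_j, step)
  new_interval(lower, upper, "ETI", level, n_draws = m)
}

# inverse of the conditional survival function at one parameter draw:
# S_{Y|x}(y) = u  <=>  G(y) = qbeta(1 - u, k, r-k+1), then invert the
# left-truncated parent CDF in closed form.
cond_sf_inverse <- function(u, target, alpha, beta) {
  k <- target$rank_k
  r <- target$r_j
  g <- stats::qbeta(u, k, r - k + 1, lower.tail = FALSE)
  fx <- ploglogis(target$x_j, alpha, beta)
  p <- fx + g * (1 - fx)
  qloglogis(p, alpha, beta)
}

#' Highest posterior density prediction interval
#'
#' Chen-Shao empirical HPD interval on the posterior-predictive sample:
#' one future value is drawn per retained posterior draw by
#' inverse-transform sampling of the conditional survival function (the
#' probability-integral Beta representation gives the inverse in closed
#' form), the draws are sorted, and the shortest contiguous window
#' containing \code{floor((1-gamma)*M) + 1} points is returned.
#'
#' @inheritParams predict_eti
#' @return An \code{ll_interval} with \code{method = "HPD"} and the
#'   predictive draws attached as attribute \code{"draws"}.
#' @export
predict_hpd <- function(target, posterior, level = 0.95) {
  stopifnot(inherits(target, "pred_target"),
            inherits(posterior, "ll_posterior"))
  m <- length(posterior$alpha)
  if (m < 100L) stop("need at least 100 posterior draws", call. = FALSE)
  gamma <- 1 - level
  u <- stats::runif(m)
  y <- vapply(seq_len(m), function(i) {
    cond_sf_inverse(u[i], target, posterior$alpha[i], posterior$beta[i])
  }, numeric(1))
  ys <- sort(y)
  w_len <- floor((1 - gamma) * m) + 1L
  if (w_len > m) w_len <- m
  widths <- ys[w_len:m] - ys[1:(m - w_len + 1L)]
  w_star <- which.min(widths)
  out <- new_interval(ys[w_star], ys[w_star + w_len - 1L], "HPD", level,
                      n_draws = m)
  attr(out, "draws") <- ys
  out
}
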