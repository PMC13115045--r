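#' Simulate one progressive experiment with latent withdrawn lifetimes
#'
#' Runs the progressive Type-II mechanism at the level of individual
#' units: \code{n} iid Log-Logistic lifetimes are drawn, and at each
#' observed failure the scheduled number of survivors is withdrawn
#' uniformly at random, retaining their (latent) lifetimes.  This makes
#' the realized future order statistics \eqn{Y_{k:r_j}} available, as
#' required by prediction-performance studies.  It is distributionally
#' identical to the uniform-spacings construction used by
#' [rprogressive()] (the two are cross-checked in the test suite).
#'
#' @param alpha,beta true Log-Logistic parameters.
#' @param scheme a \code{prog_scheme}.
#' @return A \code{prog_sample} with \code{latent} filled in.
#' @export
sim_experiment <- function(alpha, beta, scheme) {
  stopifnot(inherits(scheme, "prog_scheme"))
  check_ll_params(alpha, beta)
  censor_complete(rloglogis(scheme$n, alpha, beta), scheme)
}

#' Resolve a named prediction target for a scheme
#'
#' Maps the study-design labels to \code{(j, k)} pairs: \code{early_min}
#' is (1, 1); \code{early_median} is (1, floor(r1/2)); \code{late_min} is
#' (m, 1); \code{late_median} is (m, floor(rm/2)); \code{mid_min} is the
#' first future failure at the removal stage nearest m/2 (for schemes
#' with interior removals).
#'
#' @param scheme a \code{prog_scheme}.
#' @param target_spec one of \code{"early_min"}, \code{"early_median"},
#'   \code{"late_min"}, \code{"late_median"}, \code{"mid_min"}.
#' @return List with \code{stage_j} and \code{rank_k}.
#' @export
resolve_target <- function(scheme,
                           target_spec = c("early_min", "early_median",
                                           "late_min", "late_median",
                                           "mid_min")) {
  target_spec <- match.arg(target_spec)
  r <- scheme$removals
  m <- scheme$m
  jk <- switch(target_spec,
    early_min = c(1L, 1L),
    early_median = c(1L, max(1L, r[1] %/% 2L)),
    late_min = c(m, 1L),
    late_median = c(m, max(1L, r[m] %/% 2L)),
    mid_min = {
      stages <- which(r >= 1L)
      if (!length(stages)) stop("scheme has no removals", call. = FALSE)
      c(stages[which.min(abs(stages - m / 2))], 1L)
    })
  if (r[jk[1]] < jk[2]) {
    stop(sprintf("target %s infeasible: r[%d] = %d < k = %d",
                 target_spec, jk[1], r[jk[1]], jk[2]), call. = FALSE)
  }
  list(stage_j = jk[1], rank_k = jk[2])
}

# realized future order statistic from the latent withdrawn lifetimes
realized_target <- function(sample, stage_j, rank_k) {
  lat <- sample$latent
  if (is.null(lat)) stop("sample carries no latent lifetimes", call. = FALSE)
  lat[[stage_j]][rank_k]
}

#' Monte Carlo study of estimation performance
#'
#' Replicates the experiment, fits the MLE (and optionally the Bayes
#' estimators under the supplied priors) per replicate, and reports Mean,
#' SD, RMSE, and Wald/credible-interval coverage (CP) and average length
#' (AL) for both parameters.  Replicates with a non-converged Newton fit
#' are re-drawn; the redraw count is reported.
#'
#' @param alpha,beta true parameter values.
#' @param scheme a \code{prog_scheme}.
#' @param n_reps number of Monte Carlo replications.
#' @param level confidence/credible level (default 0.95).
#' @param priors optional named list of \code{ll_prior} kinds to include
#'   Bayesian estimates, e.g. \code{list(prior0 = "jeffreys",
#'   prior1 = "empirical")}; NULL for frequentist only.
#' @param mcmc list of MCMC settings (\code{n_iter}, \code{burn_in},
#'   \code{thin}) used when \code{priors} is non-NULL.
#' @return Data frame with one row per (method, parameter):
#'   columns \code{method}, \code{parameter}, \code{mean}, \code{sd},
#'   \code{rmse}, \code{cp}, \code{al}; attribute \code{"n_redraws"}.
#' @export
sim_estimation <- function(alpha, beta, scheme, n_reps = 1000L,
                           level = 0.95, priors = NULL,
                           mcmc = list(n_iter = 10000L, burn_in = 2000L,
                                       thin = 10L)) {
  methods <- c("mle", names(priors))
  est <- array(NA_real_, c(n_reps, length(methods), 2L),
               dimnames = list(NULL, methods, c("alpha", "beta")))
  cover <- array(NA_real_, dim(est), dimnames = dimnames(est))
  alen <- array(NA_real_, dim(est), dimnames = dimnames(est))
  truth <- c(alpha, beta)
  n_redraws <- 0L
  for (s in seq_len(n_reps)) {
    repeat {
      smp <- sim_experiment(alpha, beta, scheme)
      fit <- fit_loglogis(smp)
      if (fit$converged) break
      n_redraws <- n_redraws + 1L
    }
    est[s, "mle", ] <- c(fit$alpha, fit$beta)
    ci <- wald_ci(fit, level)
    cover[s, "mle", ] <- ci[, 1] <= truth & truth <= ci[, 2]
    alen[s, "mle", ] <- ci[, 2] - ci[, 1]
    for (pn in names(priors)) {
      pr <- ll_prior(priors[[pn]], fit = fit)
      post <- mh_gibbs(smp, pr, init = c(fit$alpha, fit$beta),
                       n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
                       thin = mcmc$thin)
      xi <- 1 - level
      sa <- posterior_summary(post, function(a, b) a, xi)
      sb <- posterior_summary(post, function(a, b) b, xi)
      est[s, pn, ] <- c(sa$estimate, sb$estimate)
      cover[s, pn, ] <- c(
        sa$interval[1] <= alpha && alpha <= sa$interval[2],
        sb$interval[1] <= beta && beta <= sb$interval[2])
      alen[s, pn, ] <- c(diff(sa$interval), diff(sb$interval))
    }
  }
  rows <- expand.grid(method = methods, parameter = c("alpha", "beta"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    mth <- rows$method[i]
    pp <- rows$parameter[i]
    e <- est[, mth, pp]
    data.frame(method = mth, parameter = pp,
               mean = mean(e), sd = stats::sd(e),
               rmse = sqrt(mean((e - truth[match(pp, c("alpha", "beta"))])^2)),
               cp = mean(cover[, mth, pp]),
               al = mean(alen[, mth, pp]))
  }))
  attr(out, "n_redraws") <- n_redraws
  out
}

#' Monte Carlo study of point-prediction performance
#'
#' Replicates the experiment retaining the latent withdrawn lifetimes,
#' computes the requested point predictors per replicate, and reports
#' Bias and mean squared prediction error (MSPE) against the realized
#' future failure time:
#' \deqn{\mathrm{Bias} = N^{-1}\sum_s (\hat Y^{(s)} - Y^{(s)}), \quad
#'   \mathrm{MSPE} = N^{-1}\sum_s (\hat Y^{(s)} - Y^{(s)})^2.}
#'
#' @inheritParams sim_estimation
#' @param target_spec target label, see [resolve_target()].
#' @param methods subset of \code{c("BUP", "CMP")}; Bayesian predictors
#'   are added per prior in \code{priors}.
#' @return Data frame with columns \code{method}, \code{bias},
#'   \code{mspe}; attribute \code{"n_redraws"}.
#' @export
sim_point_prediction <- function(alpha, beta, scheme,
                                 target_spec = "late_min",
                                 n_reps = 1000L,
                                 methods = c("BUP", "CMP"),
                                 priors = NULL,
                                 mcmc = list(n_iter = 10000L,
                                             burn_in = 2000L, thin = 10L)) {
  jk <- resolve_target(scheme, target_spec)
  all_methods <- c(methods, if (length(priors)) paste0("BP_", names(priors)))
  err <- matrix(NA_real_, n_reps, length(all_methods),
                dimnames = list(NULL, all_methods))
  n_redraws <- 0L
  for (s in seq_len(n_reps)) {
    repeat {
      smp <- sim_experiment(alpha, beta, scheme)
      fit <- fit_loglogis(smp)
      if (fit$converged) break
      n_redraws <- n_redraws + 1L
    }
    tg <- pred_target(smp, jk$stage_j, jk$rank_k)
    y_obs <- realized_target(smp, jk$stage_j, jk$rank_k)
    if ("BUP" %in% methods) {
      mom <- cond_moments(tg, fit$alpha, fit$beta, want_variance = FALSE,
                          rel_tol = 1e-8)
      err[s, "BUP"] <- mom$mean - y_obs
    }
    if ("CMP" %in% methods) {
      err[s, "CMP"] <- predict_cmp(tg, fit)$value - y_obs
    }
    for (pn in names(priors)) {
      pr <- ll_prior(priors[[pn]], fit = fit)
      post <- mh_gibbs(smp, pr, init = c(fit$alpha, fit$beta),
                       n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
                       thin = mcmc$thin)
      err[s, paste0("BP_", pn)] <- predict_bp(tg, post)$value - y_obs
    }
  }
  out <- data.frame(method = all_methods,
                    bias = colMeans(err),
                    mspe = colMeans(err^2),
                    row.names = NULL)
  attr(out, "n_redraws") <- n_redraws
  out
}

#' Monte Carlo study of interval-prediction performance
#'
#' As [sim_point_prediction()], but per replicate builds the requested
#' prediction intervals at nominal level \code{level} and reports the
#' empirical coverage probability (CP) and average length (AL).
#'
#' @inheritParams sim_point_prediction
#' @param methods subset of \code{c("PPI")}; \code{"ETI_<prior>"} and
#'   \code{"HPD_<prior>"} are added per prior in \code{priors}.
#' @param level nominal level \code{1 - gamma} (default 0.95).
#' @return Data frame with columns \code{method}, \code{cp}, \code{al};
#'   attribute \code{"n_redraws"}.
#' @export
sim_interval_prediction <- function(alpha, beta, scheme,
                                    target_spec = "late_min",
                                    n_reps = 1000L, level = 0.95,
                                    methods = "PPI",
                                    priors = NULL,
                                    mcmc = list(n_iter = 10000L,
                                                burn_in = 2000L,
                                                thin = 10L)) {
  jk <- resolve_target(scheme, target_spec)
  all_methods <- c(methods,
                   if (length(priors)) c(paste0("ETI_", names(priors)),
                                         paste0("HPD_", names(priors))))
  hit <- matrix(NA_real_, n_reps, length(all_methods),
                dimnames = list(NULL, all_methods))
  len <- matrix(NA_real_, n_reps, length(all_methods),
                dimnames = list(NULL, all_methods))
  n_redraws <- 0L
  record <- function(s, mth, iv, y_obs) {
    hit[s, mth] <<- iv$lower <= y_obs && y_obs <= iv$upper
    len[s, mth] <<- iv$upper - iv$lower
  }
  for (s in seq_len(n_reps)) {
    repeat {
      smp <- sim_experiment(alpha, beta, scheme)
      fit <- fit_loglogis(smp)
      if (fit$converged) break
      n_redraws <- n_redraws + 1L
    }
    tg <- pred_target(smp, jk$stage_j, jk$rank_k)
    y_obs <- realized_target(smp, jk$stage_j, jk$rank_k)
    if ("PPI" %in% methods) {
      record(s, "PPI", predict_ppi(tg, fit, level), y_obs)
    }
    for (pn in names(priors)) {
      pr <- ll_prior(priors[[pn]], fit = fit)
      post <- mh_gibbs(smp, pr, init = c(fit$alpha, fit$beta),
                       n_iter = mcmc$n_iter, burn_in = mcmc$burn_in,
                       thin = mcmc$thin)
      record(s, paste0("ETI_", pn), predict_eti(tg, post, level), y_obs)
      record(s, paste0("HPD_", pn), predict_hpd(tg, post, level), y_obs)
    }
  }
  out <- data.frame(method = all_methods,
                    cp = colMeans(hit),
                    al = colMeans(len),
                    row.names = NULL)
  attr(out, "n_redraws") <- n_redraws
  out
}
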