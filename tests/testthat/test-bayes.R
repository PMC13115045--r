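test_that("prior construction follows the calibration rules", {
  fit <- fit_loglogis(complete_sample(bladder))
  pr <- ll_prior("empirical", fit = fit)
  expect_equal(pr$a_alpha / pr$b_alpha, fit$alpha)     # prior mean = MLE
  expect_equal(pr$a_beta / pr$b_beta, fit$beta)
  expect_equal(1 / sqrt(pr$a_alpha), 1 / sqrt(30))     # prior CV
  expect_equal(pr$b_alpha, 30 / fit$alpha)

  pj <- ll_prior("jeffreys")
  expect_equal(pj$trunc_alpha_min, 1e-4)
  expect_equal(pj$trunc_beta_min, 1.05)

  expect_error(ll_prior("empirical"), "converged")
  expect_error(ll_prior("gamma", a_alpha = 1, b_alpha = -1,
                        a_beta = 1, b_beta = 1), "positive")
})

test_that("log kernel equals log-likelihood plus prior plus Jacobian", {
  set.seed(6)
  smp <- rprogressive(3, 2, prog_scheme("early", 30, 20))
  fit <- fit_loglogis(smp)
  pr <- ll_prior("empirical", fit = fit)
  eta <- log(2.5); zeta <- log(1.9)
  eta2 <- log(3.4); zeta2 <- log(2.2)
  ref <- function(e, z) {
    a <- exp(e); b <- exp(z)
    loglik_prog(a, b, smp) +
      dgamma(a, pr$a_alpha, pr$b_alpha, log = TRUE) +
      dgamma(b, pr$a_beta, pr$b_beta, log = TRUE) + e + z
  }
  # kernel differences match the fully normalized reference differences
  expect_equal(
    log_post_kernel(eta, zeta, smp, pr) -
      log_post_kernel(eta2, zeta2, smp, pr),
    ref(eta, zeta) - ref(eta2, zeta2), tolerance = 1e-10)

  # truncated Jeffreys: flat in log-space inside, -Inf outside
  pj <- ll_prior("jeffreys")
  expect_equal(log_post_kernel(eta, zeta, smp, pj),
               loglik_prog(exp(eta), exp(zeta), smp))
  expect_identical(log_post_kernel(eta, log(1.0), smp, pj), -Inf)
  expect_identical(log_post_kernel(log(1e-5), zeta, smp, pj), -Inf)
})

test_that("sampler contracts: determinism, degenerate proposal, rates", {
  set.seed(8)
  smp <- rprogressive(3, 2, prog_scheme("early", 40, 25))
  pj <- ll_prior("jeffreys")
  set.seed(101)
  p1 <- mh_gibbs(smp, pj, n_iter = 600, burn_in = 100, thin = 5)
  set.seed(101)
  p2 <- mh_gibbs(smp, pj, n_iter = 600, burn_in = 100, thin = 5)
  expect_identical(p1$alpha, p2$alpha)
  expect_identical(p1$beta, p2$beta)

  fit <- fit_loglogis(smp)
  p0 <- suppressWarnings(           # deliberately tiny M
    mh_gibbs(smp, pj, init = c(fit$alpha, fit$beta),
             n_iter = 300, burn_in = 50, prop_sd = c(0, 0),
             adapt = FALSE))
  expect_true(all(p0$alpha == fit$alpha))
  expect_true(all(p0$beta == fit$beta))

  expect_gt(p1$accept_rate_eta, 0)
  expect_lt(p1$accept_rate_eta, 1)
  expect_error(mh_gibbs(smp, pj, n_iter = 100, burn_in = 200), "burn_in")
})

test_that("adaptive tuning lands acceptance rates near the target band", {
  set.seed(13)
  smp <- rprogressive(3, 5, prog_scheme("late", 75, 50))
  # start from a deliberately bad proposal scale
  post <- mh_gibbs(smp, ll_prior("jeffreys"), prop_sd = c(1.5, 1.5),
                   n_iter = 6000, burn_in = 2000, thin = 5)
  expect_gt(post$accept_rate_eta, 0.15)
  expect_lt(post$accept_rate_eta, 0.55)
  expect_gt(post$accept_rate_zeta, 0.15)
  expect_lt(post$accept_rate_zeta, 0.55)
})

test_that("posterior mass sits near the MLE under the flat prior", {
  set.seed(14)
  smp <- censor_complete(bladder, scheme_bladder1)
  fit <- fit_loglogis(smp)
  post <- mh_gibbs(smp, ll_prior("jeffreys"))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(mean(post$alpha) - fit$alpha), se[1])
  expect_lt(abs(mean(post$beta) - fit$beta), se[2])
  expect_equal(post$config$M, 800L)
})

test_that("MCMC marginal matches grid integration on a small posterior", {
  set.seed(15)
  smp <- rprogressive(3, 2, prog_scheme("custom", 25, 25,
                                        removals = integer(0)))
  pj <- ll_prior("jeffreys")
  post <- mh_gibbs(smp, pj, n_iter = 30000, burn_in = 2000, thin = 2)
  # independent oracle: 2-d grid integration of the flat-prior posterior
  fit <- fit_loglogis(smp)
  se <- sqrt(diag(fit$vcov))
  eta_g <- seq(log(fit$alpha) - 5 * se[1] / fit$alpha,
               log(fit$alpha) + 5 * se[1] / fit$alpha, length.out = 160)
  zeta_g <- seq(log(max(1.06, fit$beta - 5 * se[2])),
                log(fit$beta + 5 * se[2]), length.out = 160)
  lp <- outer(eta_g, zeta_g,
              Vectorize(function(e, z) log_post_kernel(e, z, smp, pj)))
  w <- exp(lp - max(lp))
  marg <- rowSums(w) / sum(w)
  # compare binned MCMC eta draws to the grid marginal (total variation)
  br <- c(-Inf, eta_g[-1] - diff(eta_g) / 2, Inf)
  counts <- table(cut(log(post$alpha), breaks = br))
  tv <- 0.5 * sum(abs(counts / sum(counts) - marg))
  expect_lt(tv, 0.05)
})

test_that("posterior summaries follow the order-statistic construction", {
  post <- constant_posterior(4, 2, m = 50)
  s <- posterior_summary(post, function(a, b) a)
  expect_equal(s$estimate, 4)
  expect_equal(s$interval, c(4, 4))

  # draws 1..1000, xi = 0.05 -> indices 25 and 975
  fake <- constant_posterior(1, 1, m = 1000)
  fake$alpha <- sample(1:1000)
  s2 <- posterior_summary(fake, function(a, b) a, xi = 0.05)
  expect_equal(s2$interval, c(25, 975))
  expect_true(all(s2$interval %in% fake$alpha))
})
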