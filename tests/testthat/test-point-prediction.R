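# helper: simulated censored sample with a valid target
make_target <- function(seed = 20, n = 40, m = 25, k = 3, alpha = 3,
                        beta = 2) {
  set.seed(seed)
  sc <- prog_scheme("early", n, m)
  smp <- rprogressive(alpha, beta, sc)
  list(smp = smp, tg = pred_target(smp, 1, k),
       fit = fit_loglogis(smp))
}

test_that("target construction validates stage and rank", {
  mt <- make_target()
  expect_equal(mt$tg$r_j, 15L)
  expect_equal(mt$tg$x_j, mt$smp$times[1])
  expect_error(pred_target(mt$smp, 2, 1), "no units withdrawn")
  expect_error(pred_target(mt$smp, 1, 16), "1..r_j")
  expect_error(pred_target(mt$smp, 99, 1), "out of range")
})

test_that("conditional density normalizes and matches closed forms", {
  set.seed(23)
  for (i in 1:8) {
    r <- sample(2:25, 1)
    k <- sample(seq_len(r), 1)
    a <- runif(1, 1, 8)
    b <- runif(1, 1, 5)
    xj <- qloglogis(runif(1, 0.05, 0.6), a, b)
    tg <- structure(list(stage_j = 1L, rank_k = k, r_j = r, x_j = xj),
                    class = "pred_target")
    # normalization over (x_j, Inf), mapped to (0,1) through the
    # truncated parent CDF (smooth integrand for any (k, r, beta))
    fx <- ploglogis(xj, a, b)
    total <- integrate(function(s) {
      y <- qloglogis(fx + s * (1 - fx), a, b)
      cond_pdf(y, tg, a, b) * (1 - fx) / dloglogis(y, a, b)
    }, 0, 1, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
    # order-statistic Beta form on a y-grid (independent dbeta routine)
    y <- xj + qloglogis(seq(0.05, 0.95, by = 0.1), a, b)
    rho <- sloglogis(y, a, b) / sloglogis(xj, a, b)
    gk <- dbeta(1 - rho, k, r - k + 1) * dloglogis(y, a, b) /
      sloglogis(xj, a, b)
    expect_equal(cond_pdf(y, tg, a, b), gk, tolerance = 1e-9)
    expect_true(all(cond_pdf(y, tg, a, b) >= 0))
    # direct alternating binomial sum, trustworthy at moderate k
    if (k <= 12) {
      ck <- exp(lgamma(r + 1) - lgamma(k) - lgamma(r - k + 1))
      v <- 0:(k - 1)
      wv <- choose(k - 1, v) * (-1)^(k - 1 - v)
      alt <- ck * vapply(rho, function(p) sum(wv * p^(r - v)), 0) *
        hloglogis(y, a, b)
      expect_equal(cond_pdf(y, tg, a, b), alt, tolerance = 1e-7)
    }
  }
  # k = 1: minimum of the truncated sample
  tg1 <- structure(list(stage_j = 1L, rank_k = 1L, r_j = 6L, x_j = 2),
                   class = "pred_target")
  y <- c(2.5, 4, 9)
  rho <- sloglogis(y, 3, 2) / sloglogis(2, 3, 2)
  expect_equal(cond_pdf(y, tg1, 3, 2),
               6 * rho^5 * dloglogis(y, 3, 2) / sloglogis(2, 3, 2),
               tolerance = 1e-12)
  # k = r = 1: plain left-truncated density
  tg11 <- structure(list(stage_j = 1L, rank_k = 1L, r_j = 1L, x_j = 2),
                    class = "pred_target")
  expect_equal(cond_pdf(y, tg11, 3, 2),
               dloglogis(y, 3, 2) / sloglogis(2, 3, 2), tolerance = 1e-12)
  # below the truncation point the density is zero by convention
  expect_equal(cond_pdf(c(0.5, 2), tg11, 3, 2), c(0, 0))
})

test_that("conditional survival matches its Beta representation and pdf", {
  set.seed(24)
  for (i in 1:8) {
    r <- sample(2:20, 1)
    k <- sample(seq_len(r), 1)
    a <- runif(1, 1, 6)
    b <- runif(1, 1, 5)
    xj <- qloglogis(runif(1, 0.1, 0.6), a, b)
    tg <- structure(list(stage_j = 1L, rank_k = k, r_j = r, x_j = xj),
                    class = "pred_target")
    expect_equal(cond_sf(xj, tg, a, b), 1, tolerance = 1e-10)
    y <- xj + qloglogis(seq(0.1, 0.9, by = 0.2), a, b)
    rho <- sloglogis(y, a, b) / sloglogis(xj, a, b)
    # alternating-sum oracle at moderate k
    if (k <= 12) {
      ck <- exp(lgamma(r + 1) - lgamma(k) - lgamma(r - k + 1))
      v <- 0:(k - 1)
      wv <- choose(k - 1, v) * (-1)^(k - 1 - v)
      alt <- ck * vapply(rho, function(p) sum(wv / (r - v) * p^(r - v)), 0)
      expect_equal(cond_sf(y, tg, a, b), alt, tolerance = 1e-7)
    }
    # survival = integral of the density over (y, Inf)
    s_quad <- vapply(y, function(y0) {
      integrate(function(t) {
        z <- y0 + t / (1 - t)
        cond_pdf(z, tg, a, b) / (1 - t)^2
      }, 0, 1, rel.tol = 1e-10)$value
    }, numeric(1))
    expect_equal(cond_sf(y, tg, a, b), s_quad, tolerance = 1e-8)
    expect_true(all(diff(cond_sf(sort(y), tg, a, b)) < 0))
  }
})

test_that("Beta medians match closed forms and symmetry", {
  expect_equal(beta_median(1, 1), 0.5)
  expect_equal(beta_median(1, 2), 1 - sqrt(0.5), tolerance = 1e-10)
  for (r in c(5, 12, 20)) {
    for (k in seq_len(r)) {
      expect_equal(beta_median(k, r), 1 - beta_median(r - k + 1, r),
                   tolerance = 1e-10)
      expect_equal(pbeta(beta_median(k, r), k, r - k + 1), 0.5,
                   tolerance = 1e-10)
    }
  }
  expect_error(beta_median(3, 2), "k <= r")
})

test_that("conditional moments agree with the Beta-quantile MC oracle", {
  set.seed(25)
  cases <- list(c(1, 5), c(3, 5), c(13, 20))
  for (cs in cases) {
    k <- cs[1]; r <- cs[2]
    a <- 3; b <- 2.5
    xj <- qloglogis(0.3, a, b)
    tg <- structure(list(stage_j = 1L, rank_k = k, r_j = r, x_j = xj),
                    class = "pred_target")
    mom <- cond_moments(tg, a, b)
    # oracle: U ~ Beta(k, r-k+1); Y = Qtrunc(U)
    u <- rbeta(2e5, k, r - k + 1)
    fx <- ploglogis(xj, a, b)
    y_mc <- qloglogis(fx + u * (1 - fx), a, b)
    se <- sd(y_mc) / sqrt(length(y_mc))
    expect_lt(abs(mom$mean - mean(y_mc)), 3 * se)
    expect_gte(mom$variance, 0)
    # second-moment identity against the same oracle
    se2 <- sd((y_mc - mean(y_mc))^2) / sqrt(length(y_mc))
    expect_lt(abs(mom$variance - var(y_mc)), 4 * se2)
  }
})

test_that("moment existence guard and degenerate concentration limit", {
  tg <- structure(list(stage_j = 1L, rank_k = 2L, r_j = 2L, x_j = 1),
                  class = "pred_target")
  expect_error(cond_moments(tg, 3, 0.9), "mean diverges")
  expect_error(cond_moments(tg, 3, 1.5), "variance diverges")
  expect_silent(cond_moments(tg, 3, 1.5, want_variance = FALSE))
  # k = r = 1 with huge beta: the truncated law collapses onto x_j
  tg1 <- structure(list(stage_j = 1L, rank_k = 1L, r_j = 1L, x_j = 3),
                   class = "pred_target")
  m50 <- cond_moments(tg1, 3, 50, want_variance = FALSE)$mean
  m200 <- cond_moments(tg1, 3, 200, want_variance = FALSE)$mean
  expect_gt(m50, 3)
  expect_lt(m200 - 3, m50 - 3)
  expect_lt(m200, 3.03)
})

test_that("quadrature is stable under tolerance halving", {
  mt <- make_target(k = 7)
  m1 <- cond_moments(mt$tg, mt$fit$alpha, mt$fit$beta, rel_tol = 1e-9)$mean
  m2 <- cond_moments(mt$tg, mt$fit$alpha, mt$fit$beta, rel_tol = 5e-10)$mean
  expect_lt(abs(m1 / m2 - 1), 1e-6)
})

test_that("CMP closed form solves the conditional-median equation", {
  mt <- make_target(k = 9)
  cmp <- predict_cmp(mt$tg, mt$fit)
  # numeric inversion oracle: S(Y) = (1 - m_{k,r}) S(x_j) on the parent
  m_kr <- beta_median(9, mt$tg$r_j)
  root <- uniroot(function(y) {
    sloglogis(y, mt$fit$alpha, mt$fit$beta) -
      (1 - m_kr) * sloglogis(mt$tg$x_j, mt$fit$alpha, mt$fit$beta)
  }, lower = mt$tg$x_j, upper = mt$tg$x_j + 100 * mt$fit$alpha,
  tol = 1e-12)$root
  expect_equal(cmp$value, root, tolerance = 1e-8)
  # the CMP is the median of the conditional law
  expect_equal(cond_sf(cmp$value, mt$tg, mt$fit$alpha, mt$fit$beta), 0.5,
               tolerance = 1e-8)
})

test_that("BUP attaches a positive delta-method variance", {
  mt <- make_target(k = 3)
  bup <- predict_bup(mt$tg, mt$fit)
  expect_gt(bup$value, mt$tg$x_j)
  expect_gt(bup$variance, 0)
  expect_gt(bup$conditional_variance, 0)
})

test_that("degenerate posterior collapses BP onto BUP", {
  mt <- make_target(k = 3)
  bup <- predict_bup(mt$tg, mt$fit)
  post <- constant_posterior(mt$fit$alpha, mt$fit$beta)
  bp <- predict_bp(mt$tg, post)
  expect_equal(bp$value, bup$value, tolerance = 1e-7)
  # total variance >= averaged conditional variance component
  expect_gte(bp$variance + 1e-12, mean(bup$conditional_variance))
})

test_that("all predictors exceed the truncation point; CMP < BUP when skewed", {
  set.seed(27)
  sc <- prog_scheme("early", 30, 20)
  for (i in 1:5) {
    smp <- rprogressive(3, 1.5, sc)
    fit <- fit_loglogis(smp)
    tg <- pred_target(smp, 1, 5)
    cmp <- predict_cmp(tg, fit)$value
    if (fit$beta * (tg$r_j - tg$rank_k + 1) > 1) {
      bup <- cond_moments(tg, fit$alpha, fit$beta,
                          want_variance = FALSE)$mean
      expect_gt(bup, tg$x_j)
      # right-skew: conditional median below conditional mean
      expect_lt(cmp, bup)
    }
    expect_gt(cmp, tg$x_j)
  }
})
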