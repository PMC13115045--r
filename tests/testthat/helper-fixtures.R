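# shared fixtures and small oracles

# complete sample (no censoring) as a prog_sample
complete_sample <- function(x) {
  n <- length(x)
  prog_sample(sort(x), prog_scheme("custom", n, n, removals = integer(0)))
}

# degenerate posterior: all draws at a single point (for BP=BUP / ETI=PPI
# identities)
constant_posterior <- function(alpha, beta, m = 200L) {
  structure(list(alpha = rep(alpha, m), beta = rep(beta, m),
                 accept_rate_eta = 0, accept_rate_zeta = 0,
                 prop_sd = c(eta = 0, zeta = 0),
                 config = list(n_iter = m, burn_in = 0L, thin = 1L, M = m),
                 eta_chain = rep(log(alpha), m),
                 zeta_chain = rep(log(beta), m)),
            class = "ll_posterior")
}

# central finite-difference gradient of a scalar function of (alpha, beta)
fd_gradient <- function(f, a, b, h = 1e-6) {
  c((f(a * (1 + h), b) - f(a * (1 - h), b)) / (2 * a * h),
    (f(a, b * (1 + h)) - f(a, b * (1 - h))) / (2 * b * h))
}

bladder <- ll_data("bladder")$values
guinea <- ll_data("guinea")$values
scheme_bladder1 <- prog_scheme("custom", 128, 64,
                               removals = c(20, 15, 15, 10, 4))
scheme_guinea1 <- prog_scheme("custom", 72, 36, removals = c(15, 10, 6, 5))
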