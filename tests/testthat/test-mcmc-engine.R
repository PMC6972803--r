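test_that("joint log posterior equals an independent term-by-term sum", {
  data <- tiny_survey(I = 2, J = 3, seed = 8)
  par <- random_obs_params(data, seed = 4)
  X <- matrix(rnorm(6), 3, 2)
  st <- selection_state(gamma = c(1, 0), beta = c(0.5, -1), a0 = 0.3,
                        tau = 2)
  focal <- 2
  lam <- exp(compute_log_intensity(par, data))
  mu <- st$a0 + drop(X %*% (st$gamma * st$beta))
  want <- sum(dpois(data$counts, lam, log = TRUE)) +
    sum(dnorm(par$a[2, ], mu, 1 / sqrt(2), log = TRUE)) +
    sum(dnorm(par$a[1, ], 0, 10, log = TRUE)) +
    sum(dnorm(par$e_alive, 0, 10, log = TRUE)) +
    dnorm(par$p_alive[2], 0, 10, log = TRUE) +
    2 * log(0.5) + sum(dnorm(st$beta, 0, 10, log = TRUE)) +
    dnorm(st$a0, 0, 10, log = TRUE) + log(1 / (1000 - 1e-4))
  expect_equal(log_posterior(par, st, data, X, focal), want,
               tolerance = 1e-10)

  # precision outside the uniform support voids the posterior
  st_bad <- st; st_bad$tau <- 2000
  expect_identical(log_posterior(par, st_bad, data, X, focal), -Inf)
})

test_that("sampler output is deterministic given the seed, with the
           configured shapes", {
  spec <- scenario_spec(J = 12, I = 3, R = 3, active_set = 1,
                        true_beta = 0.5, seed = 17)
  sim <- simulate_survey(spec)
  cfg <- mcmc_config(n_chains = 2, n_burn = 100, n_iter = 400, thin = 20,
                     seed = 5)
  d1 <- run_mcmc(sim$data, sim$X, cfg)
  d2 <- run_mcmc(sim$data, sim$X, cfg)
  expect_identical(d1$chains, d2$chains)
  for (ch in d1$chains) {
    expect_identical(dim(ch$gamma), c(20L, 3L))
    expect_identical(dim(ch$a_b), c(20L, 12L))
    expect_length(ch$tau, 20L)
    expect_true(all(ch$gamma %in% 0:1))
    expect_true(all(ch$tau >= 1e-4 & ch$tau <= 1000))
  }
})

test_that("with the observation level bypassed, beta matches its conjugate
           posterior", {
  set.seed(23)
  J <- 60
  x <- scale(rnorm(J))[, 1]
  tau <- 4
  a_b <- 1 + 0.8 * x + rnorm(J, 0, 1 / sqrt(tau))
  out <- run_selection_gibbs(a_b, matrix(x), n_burn = 500, n_iter = 20000,
                             thin = 2, seed = 31, fixed_tau = tau)
  keep <- out$gamma[, 1] == 1
  expect_gt(mean(keep), 0.99)   # strong signal: nearly always included
  # analytic conditional given gamma = 1 (a0 integrated by Gibbs; compare
  # against the joint conjugate posterior of (a0, beta))
  Xd <- cbind(1, x)
  prec <- diag(c(0.01, 0.01)) + tau * crossprod(Xd)
  mean_post <- solve(prec, tau * crossprod(Xd, a_b))
  sd_post <- sqrt(solve(prec)[2, 2])
  b <- out$beta[keep, 1]
  expect_lt(abs(mean(b) - mean_post[2]), 3 * mcse_batch(b) + 1e-3)
  expect_lt(abs(sd(b) - sd_post) / sd_post, 0.1)
})

test_that("metropolis acceptance lands in the adapted band on a default
           scenario", {
  spec <- scenario_spec(J = 40, I = 3, R = 3, active_set = 2,
                        true_beta = 0.5, seed = 41)
  sim <- simulate_survey(spec)
  d <- run_mcmc(sim$data, sim$X,
                mcmc_config(n_chains = 1, n_burn = 800, n_iter = 1500,
                            thin = 10, seed = 7))
  acc <- d$chains[[1]]$accept
  expect_true(all(acc > 0.1 & acc < 0.6))
})

test_that("cross-chain agreement arithmetic and convergence behave", {
  # identical chains -> zero difference, pass
  g <- matrix(rbinom(40, 1, 0.5), 20, 2)
  same <- fake_draws(list(g, g))
  ag <- check_chain_agreement(same)
  expect_equal(unname(ag$max_diff), c(0, 0))
  expect_true(ag$pass)

  # p_r of (0.9, 0.8, 0.85) -> max difference 0.1, fails at 0.05
  mk <- function(p) matrix(c(rep(1, round(20 * p)), rep(0, 20 - round(20 * p))))
  tri <- fake_draws(list(mk(0.9), mk(0.8), mk(0.85)))
  ag3 <- check_chain_agreement(tri)
  expect_equal(unname(ag3$max_diff), 0.1, tolerance = 1e-12)
  expect_false(ag3$pass)

  expect_error(check_chain_agreement(fake_draws(list(g))),
               class = "abundsel_single_chain")

  # longer chains agree better on the same toy posterior
  spec <- scenario_spec(J = 25, I = 3, R = 2, active_set = 1,
                        true_beta = 0.3, seed = 3)
  sim <- simulate_survey(spec)
  d_short <- run_mcmc(sim$data, sim$X,
                      mcmc_config(n_chains = 2, n_burn = 300, n_iter = 400,
                                  thin = 2, seed = 2))
  d_long <- run_mcmc(sim$data, sim$X,
                     mcmc_config(n_chains = 2, n_burn = 300, n_iter = 8000,
                                 thin = 2, seed = 2))
  expect_lte(max(check_chain_agreement(d_long)$max_diff),
             max(check_chain_agreement(d_short)$max_diff) + 0.02)
})

test_that("zero-effort units are dropped with a warning, not an error", {
  data <- tiny_survey(I = 3, J = 6, seed = 44)
  data$km[2] <- 0
  d0 <- survey_dataset(data$counts, data$surface, data$km)
  X <- matrix(rnorm(12), 6, 2)
  expect_warning(
    d <- run_mcmc(d0, X, mcmc_config(n_chains = 1, n_burn = 50,
                                     n_iter = 100, thin = 10, seed = 1)),
    "zero km")
  expect_length(d$units, 5L)
})
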