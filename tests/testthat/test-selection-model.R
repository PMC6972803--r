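test_that("regression mean applies only included covariates", {
  X <- matrix(c(0.5, 3), 1, 2)
  st <- selection_state(gamma = c(1, 0), beta = c(2, 99), a0 = 1)
  expect_equal(regression_mean(st, X), 2)   # 1 + 2 * 0.5; inactive ignored

  X2 <- matrix(rnorm(12), 4, 3)
  st0 <- selection_state(gamma = rep(0, 3), beta = rnorm(3), a0 = -2)
  expect_equal(regression_mean(st0, X2), rep(-2, 4))
  stz <- selection_state(gamma = c(1, 1, 0), beta = c(0.3, 0, 1), a0 = 0)
  sto <- selection_state(gamma = c(1, 0, 0), beta = c(0.3, 0, 1), a0 = 0)
  expect_equal(regression_mean(stz, X2), regression_mean(sto, X2))
})

test_that("inclusion full conditional matches two-point enumeration", {
  set.seed(2)
  X <- matrix(rnorm(8), 4, 2)
  a_b <- rnorm(4)
  st <- selection_state(gamma = c(1, 0), beta = c(0.8, -0.4), a0 = 0.2,
                        tau = 3)
  for (r in 1:2) {
    lik <- sapply(0:1, function(g) {
      s2 <- st; s2$gamma[r] <- g
      sum(dnorm(a_b, regression_mean(s2, X), 1 / sqrt(st$tau), log = TRUE))
    })
    want <- 1 / (1 + exp(lik[1] - lik[2]))   # Bernoulli(0.5) prior cancels
    expect_equal(gamma_full_conditional(r, st, a_b, X), want,
                 tolerance = 1e-12)
  }
  # beta_r = 0 -> likelihood ratio 1 -> exactly 0.5
  st0 <- selection_state(gamma = c(1, 1), beta = c(0, 0.4), a0 = 0, tau = 3)
  expect_identical(gamma_full_conditional(1, st0, a_b, X), 0.5)
})

test_that("inclusion probability saturates for a strong matching effect and
           ignores permutation of other covariates", {
  set.seed(6)
  J <- 200
  X <- scale(matrix(rnorm(J * 3), J, 3))
  a_b <- drop(0.5 * X[, 2] + rnorm(J, 0, 1 / sqrt(25)))
  st <- selection_state(gamma = c(0, 0, 0), beta = c(0, 0.5, 0), tau = 25)
  expect_gt(gamma_full_conditional(2, st, a_b, X), 0.99)

  # permuting the other covariates' indices leaves p unchanged
  st2 <- selection_state(gamma = c(1, 1, 0), beta = c(0.3, 0.5, -0.2),
                         a0 = 0.1, tau = 25)
  p_ref <- gamma_full_conditional(2, st2, a_b, X)
  stp <- selection_state(gamma = st2$gamma[c(3, 2, 1)],
                         beta = st2$beta[c(3, 2, 1)], a0 = 0.1, tau = 25)
  expect_equal(gamma_full_conditional(2, stp, a_b, X[, c(3, 2, 1)]), p_ref,
               tolerance = 1e-12)
})

test_that("coefficient draws follow the prior when excluded and the
           conjugate conditional when included", {
  set.seed(9)
  X <- matrix(rnorm(30), 10, 3)
  a_b <- rnorm(10)
  st <- selection_state(gamma = c(0, 1, 0), beta = rep(0, 3), tau = 2)
  draws <- replicate(10000, draw_beta_conditional(1, st, a_b, X))
  expect_lt(abs(sd(draws) - 10) / 10, 0.02)   # prior sd = 1/sqrt(0.01)
  expect_lt(abs(mean(draws)), 3 * 10 / sqrt(10000))

  # conjugate moments vs closed-form weighted least squares (J = 3)
  X3 <- matrix(c(1, 2, -1), 3, 1)
  y3 <- c(0.5, 1.1, -0.7)
  stc <- selection_state(gamma = 1, beta = 0, a0 = 0, tau = 4)
  m <- beta_conditional_moments(1, stc, y3, X3)
  prec_want <- 0.01 + 4 * sum(X3^2)
  expect_equal(m$precision, prec_want, tolerance = 1e-10)
  expect_equal(m$mean, 4 * sum(X3 * y3) / prec_want, tolerance = 1e-10)

  # vague-prior large-J limit approaches the OLS slope
  set.seed(10)
  Jb <- 10000
  xb <- rnorm(Jb)
  yb <- 0.7 * xb + rnorm(Jb)
  stb <- selection_state(gamma = 1, beta = 0, a0 = 0, tau = 1)
  mb <- beta_conditional_moments(1, stb, yb, matrix(xb))
  ols <- unname(coef(lm(yb ~ xb))[2])
  expect_lt(abs(mb$mean - ols), 0.02)
})

test_that("tau draws match a rejection-sampling oracle and respect the
           support", {
  X <- matrix(rnorm(6), 6, 1)
  st <- selection_state(gamma = 0, beta = 0, a0 = 0, tau = 1)
  # residuals chosen so the Gamma(4, SSR/2) mass straddles the upper bound
  a_b <- regression_mean(st, X) + sqrt(0.01 / 6) * c(1, -1, 1, -1, 1, -1)
  set.seed(11)
  ours <- draw_tau_conditional(st, a_b, X, n = 5000)
  expect_true(all(ours >= 1e-4 & ours <= 1000))
  ssr <- sum((a_b - regression_mean(st, X))^2)
  raw <- rgamma(40000, shape = 4, rate = ssr / 2)
  oracle <- raw[raw >= 1e-4 & raw <= 1000][1:5000]
  ks <- suppressWarnings(ks.test(ours, oracle))
  expect_gt(ks$p.value, 0.05)

  # SSR -> 0 concentrates at the upper bound
  expect_equal(draw_tau_conditional(st, regression_mean(st, X), X, n = 50),
               rep(1000, 50))
})

test_that("successive-conditional simulation leaves the priors invariant
           (Geweke-style joint check)", {
  # Alternate a_b ~ p(a_b | theta) with the Gibbs updates of
  # (a0, gamma, beta); if the conditionals are correct the chain's
  # stationary law for theta is the prior. tau is held at 1: with the
  # uniform precision prior the successive-conditional chain can lock
  # into self-confirming high-precision states and mixes too slowly to
  # test anything; tau's own conditional is checked against a rejection
  # oracle elsewhere.
  set.seed(13)
  J <- 5; R <- 2
  X <- scale(matrix(rnorm(J * R), J, R))
  n <- 20000
  st <- selection_state(gamma = rbinom(R, 1, 0.5),
                        beta = rnorm(R, 0, 10),
                        a0 = rnorm(1, 0, 10), tau = 1)
  g1 <- b1 <- a0_tr <- numeric(n)
  for (t in seq_len(n)) {
    a_b <- rnorm(J, regression_mean(st, X), 1 / sqrt(st$tau))
    st$a0 <- draw_a0_conditional(st, a_b, X)
    for (r in seq_len(R)) {
      st$gamma[r] <- rbinom(1, 1, gamma_full_conditional(r, st, a_b, X))
      st$beta[r] <- draw_beta_conditional(r, st, a_b, X)
    }
    g1[t] <- st$gamma[1]; b1[t] <- st$beta[1]; a0_tr[t] <- st$a0
  }
  expect_lt(abs(mean(g1) - 0.5), 3 * mcse_batch(g1))
  expect_lt(abs(mean(b1) - 0), 3 * mcse_batch(b1))
  expect_lt(abs(mean(b1^2) - 100), 3 * mcse_batch(b1^2))
  expect_lt(abs(mean(a0_tr) - 0), 3 * mcse_batch(a0_tr))
  expect_lt(abs(mean(a0_tr^2) - 100), 3 * mcse_batch(a0_tr^2))
})
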