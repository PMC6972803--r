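test_that("log intensity assembles the four additive terms", {
  # single species/unit, hand sum: log(2) + 0.5 - 0.3 + 0.1
  counts <- array(0L, c(2, 1, 2))
  data <- survey_dataset(counts, surface = 2, km = 1)
  par <- observation_params(a = matrix(c(0, 0.5), 2, 1),
                            e_alive = -0.3, p_alive = c(0, 0.1))
  ll <- compute_log_intensity(par, data)
  expect_equal(ll[2, 1, 2], log(2) + 0.5 - 0.3 + 0.1)
  expect_equal(ll[2, 1, 2], 0.9931, tolerance = 1e-4)

  # all free parameters 0, S = V = 1 -> every entry 0
  d0 <- survey_dataset(array(0L, c(2, 3, 2)), surface = rep(1, 3),
                       km = rep(1, 3))
  p0 <- observation_params(matrix(0, 2, 3), rep(0, 3), rep(0, 2))
  expect_true(all(compute_log_intensity(p0, d0) == 0))
})

test_that("likelihood equals a term-by-term Poisson oracle and handles
           empty counts", {
  data <- tiny_survey(I = 2, J = 2, seed = 7)
  par <- random_obs_params(data, seed = 2)
  lam <- exp(compute_log_intensity(par, data))
  expect_equal(survey_log_likelihood(par, data),
               oracle_poisson_loglik(data$counts, lam), tolerance = 1e-10)

  zero <- survey_dataset(array(0L, dim(data$counts)), data$surface, data$km)
  expect_equal(survey_log_likelihood(par, zero),
               -sum(exp(compute_log_intensity(par, zero))), tolerance = 1e-10)
})

test_that("a common intensity maximizes the likelihood at the count mean", {
  data <- tiny_survey(I = 2, J = 3, seed = 12)
  # parametrize a common lambda through a shared abundance shift
  ll_at <- function(lam) {
    p <- observation_params(matrix(log(lam), 2, 3) -
                              matrix(log(data$surface * data$km), 2, 3,
                                     byrow = TRUE),
                            e_alive = log(data$km), p_alive = c(0, 0))
    survey_log_likelihood(p, data)
  }
  opt <- optimize(ll_at, c(0.01, 50), maximum = TRUE)
  expect_equal(opt$maximum, mean(data$counts), tolerance = 1e-4)
})

test_that("likelihood is invariant to the (a + c, e - c) translation", {
  data <- tiny_survey(I = 3, J = 4, seed = 3)
  par <- random_obs_params(data, seed = 5)
  base <- survey_log_likelihood(par, data)
  for (c0 in c(-2, 0.7)) {
    shifted <- observation_params(par$a + c0, par$e_alive - c0, par$p_alive,
                                  e_dead = log(data$km) - c0)
    expect_equal(survey_log_likelihood(shifted, data), base,
                 tolerance = 1e-10)
  }
})

test_that("natural and reduced parametrizations give identical likelihoods", {
  set.seed(14)
  data <- tiny_survey(I = 3, J = 4, seed = 14)
  nat <- list(A = matrix(exp(rnorm(12)), 3, 4),
              E = matrix(exp(rnorm(8)), 4, 2),
              P = matrix(runif(6, 0.05, 1), 3, 2),
              beta_const = 1.7)
  red <- natural_to_reduced(nat, data)
  lam_nat <- array(NA_real_, dim(data$counts))
  for (k in 1:2)
    lam_nat[, , k] <- t(data$surface * t(nat$A)) *
      matrix(nat$E[, k], 3, 4, byrow = TRUE) * nat$P[, k]
  expect_equal(survey_log_likelihood(red, data),
               oracle_poisson_loglik(data$counts, lam_nat), tolerance = 1e-10)

  # constraint zeros are exact
  expect_identical(red$p_alive[1], 0)

  # invariance to beta, and to rescaling all efforts by c with densities
  # divided by c (beta follows the effort scale): the data law is unchanged
  nat2 <- nat; nat2$beta_const <- 0.2
  nat3 <- nat; nat3$E <- nat$E * 5; nat3$A <- nat$A / 5
  nat3$beta_const <- nat$beta_const * 5
  for (alt in list(nat2, nat3))
    expect_equal(survey_log_likelihood(natural_to_reduced(alt, data), data),
                 survey_log_likelihood(red, data), tolerance = 1e-10)

  # symmetric detectability: all P equal, beta = 1 -> p offsets vanish
  natS <- nat; natS$P <- matrix(0.4, 3, 2); natS$beta_const <- 1
  redS <- natural_to_reduced(natS, data)
  expect_equal(redS$p_alive, rep(0, 3), tolerance = 1e-12)
  expect_equal(redS$a, log(natS$A) + log(0.4), tolerance = 1e-12)
})

test_that("every free parameter is locally identifiable", {
  data <- tiny_survey(I = 2, J = 2, seed = 20)
  par <- random_obs_params(data, seed = 3)
  base <- survey_log_likelihood(par, data)
  bump <- function(p) expect_false(isTRUE(all.equal(
    survey_log_likelihood(p, data), base, tolerance = 1e-9)))
  for (i in 1:2) for (j in 1:2) {
    p <- par; p$a[i, j] <- p$a[i, j] + 0.01; bump(p)
  }
  for (j in 1:2) { p <- par; p$e_alive[j] <- p$e_alive[j] + 0.01; bump(p) }
  p <- par; p$p_alive[2] <- p$p_alive[2] + 0.01; bump(p)
})

test_that("malformed natural parameters and zero-effort units are rejected", {
  data <- tiny_survey(I = 2, J = 2, seed = 1)
  nat <- list(A = matrix(1, 2, 2), E = matrix(1, 2, 2),
              P = matrix(c(0.5, -0.1, 0.5, 0.5), 2, 2), beta_const = 1)
  expect_error(natural_to_reduced(nat, data),
               class = "abundsel_non_positive_param")
  d0 <- survey_dataset(data$counts, data$surface, km = c(1, 0))
  p <- random_obs_params(data, seed = 2)
  expect_error(compute_log_intensity(p, d0),
               class = "abundsel_zero_effort_unit")
})
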