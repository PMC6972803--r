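## Selection level: Kuo-Mallick spike-and-slab regression of focal-species
## log-relative abundance on standardized covariates.
##
## Model:  a_bj ~ Normal(mu_j, precision tau),
##         mu_j = a0 + sum_r gamma_r * beta_r * X_jr,
## priors: gamma_r ~ Bernoulli(0.5), beta_r ~ Normal(0, precision 0.01),
##         a0 ~ Normal(0, precision 0.01), tau ~ Uniform(0.0001, 1000).
## All Normal second parameters are precisions (inverse variances).

TAU_LO <- 1e-4
TAU_HI <- 1e3
PRIOR_PREC_BETA <- 0.01
PRIOR_PREC_A0 <- 0.01

#' Selection-level parameter state
#'
#' @param gamma binary inclusion indicators, length R.
#' @param beta regression coefficients, length R.
#' @param a0 intercept.
#' @param tau precision of the focal log-abundance noise, in
#'   `[0.0001, 1000]`.
#' @return an object of class `selection_state`.
#' @export
selection_state <- function(gamma, beta, a0 = 0, tau = 1) {
  gamma <- as.integer(gamma)
  if (!all(gamma %in% 0:1)) abort("gamma must be binary", "schema")
  if (length(beta) != length(gamma))
    abort("gamma/beta length mismatch", "bad_dimension")
  if (tau < TAU_LO || tau > TAU_HI)
    abort("tau outside prior support [0.0001, 1000]", "schema")
  structure(list(gamma = gamma, beta = as.numeric(beta),
                 a0 = as.numeric(a0), tau = as.numeric(tau)),
            class = "selection_state")
}

#' Regression mean of the selection level
#'
#' `mu_j = a0 + sum_r gamma_r beta_r X_jr`; an excluded covariate
#' (`gamma_r = 0`) contributes nothing regardless of `beta_r`.
#'
#' @param state a [selection_state()].
#' @param X J x R covariate matrix.
#' @return length-J numeric vector.
#' @export
regression_mean <- function(state, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(state$gamma))
    abort("X column count must match state R", "bad_dimension")
  drop(state$a0 + X %*% (state$gamma * state$beta))
}

#' Full conditional inclusion probability of one covariate
#'
#' Posterior probability that `gamma_r = 1` given everything else, with
#' `beta_r` held at its current value: the Bernoulli(0.5) prior times the
#' Normal likelihood of `a_b` under `mu` computed with `gamma_r` set to 1
#' versus 0, evaluated on the log scale.
#'
#' @param r covariate index.
#' @param state a [selection_state()].
#' @param a_b length-J focal log-relative abundance vector.
#' @param X J x R covariate matrix.
#' @return probability in (0, 1).
#' @export
gamma_full_conditional <- function(r, state, a_b, X) {
  X <- as.matrix(X)
  R <- length(state$gamma)
  if (r < 1 || r > R) abort("covariate index out of range", "bad_index")
  ## mu without covariate r's contribution
  g0 <- state$gamma; g0[r] <- 0L
  mu0 <- state$a0 + drop(X %*% (g0 * state$beta))
  b <- state$beta[r]; x <- X[, r]
  z <- a_b - mu0
  ## SSR(gamma_r = 0) - SSR(gamma_r = 1) = 2 b <x,z> - b^2 <x,x>
  logit <- 0.5 * state$tau * (2 * b * sum(x * z) - b^2 * sum(x * x))
  1 / (1 + exp(-logit))
}

#' Conditional moments and draw of one regression coefficient
#'
#' Under the Kuo-Mallick scheme, when `gamma_r = 0` the coefficient is
#' detached from the data and refreshes from its Normal(0, precision 0.01)
#' prior; when `gamma_r = 1` it is drawn from the conjugate Normal full
#' conditional combining that prior with the data precision
#' `tau * sum_j X_jr^2` given the partial residuals.
#'
#' @inheritParams gamma_full_conditional
#' @return `beta_conditional_moments`: `list(mean, precision)` of the
#'   `gamma_r = 1` full conditional. `draw_beta_conditional`: one draw of
#'   `beta_r` respecting the current `gamma_r`.
#' @export
beta_conditional_moments <- function(r, state, a_b, X) {
  X <- as.matrix(X)
  if (r < 1 || r > length(state$gamma))
    abort("covariate index out of range", "bad_index")
  g0 <- state$gamma; g0[r] <- 0L
  mu0 <- state$a0 + drop(X %*% (g0 * state$beta))
  x <- X[, r]
  prec <- PRIOR_PREC_BETA + state$tau * sum(x * x)
  list(mean = state$tau * sum(x * (a_b - mu0)) / prec, precision = prec)
}

#' @rdname beta_conditional_moments
#' @export
draw_beta_conditional <- function(r, state, a_b, X) {
  if (state$gamma[r] == 0L) {
    rnorm(1, 0, 1 / sqrt(PRIOR_PREC_BETA))
  } else {
    m <- beta_conditional_moments(r, state, a_b, X)
    rnorm(1, m$mean, 1 / sqrt(m$precision))
  }
}

#' Full conditional draw of the noise precision tau
#'
#' With a Uniform(0.0001, 1000) prior on the precision, the full
#' conditional is Gamma(shape `J/2 + 1`, rate `SSR/2`) truncated to the
#' prior support, where `SSR = sum_j (a_bj - mu_j)^2`; sampled by inverse
#' CDF on the truncated region. When the Gamma mass lies almost entirely
#' outside the support the draw collapses to the nearer bound (e.g.
#' `SSR -> 0` concentrates draws at 1000).
#'
#' @inheritParams gamma_full_conditional
#' @param n number of draws.
#' @return numeric vector of draws in `[0.0001, 1000]`.
#' @export
draw_tau_conditional <- function(state, a_b, X, n = 1L) {
  mu <- regression_mean(state, X)
  ssr <- sum((a_b - mu)^2)
  J <- length(a_b)
  shape <- J / 2 + 1
  rate <- ssr / 2
  if (rate <= 0) return(rep(TAU_HI, n))
  flo <- pgamma(TAU_LO, shape, rate = rate)
  fhi <- pgamma(TAU_HI, shape, rate = rate)
  if (fhi - flo < 1e-14) {
    return(rep(if (flo > 0.5) TAU_LO else TAU_HI, n))
  }
  u <- runif(n, flo, fhi)
  pmin(TAU_HI, pmax(TAU_LO, qgamma(u, shape, rate = rate)))
}

#' Full conditional draw of the intercept
#'
#' Conjugate Normal update combining the Normal(0, precision 0.01) prior
#' with the likelihood of `a_b` around the covariate part of `mu`.
#'
#' @inheritParams gamma_full_conditional
#' @return one draw of `a0`.
#' @export
draw_a0_conditional <- function(state, a_b, X) {
  eta <- regression_mean(state, X) - state$a0
  J <- length(a_b)
  prec <- PRIOR_PREC_A0 + J * state$tau
  m <- state$tau * sum(a_b - eta) / prec
  rnorm(1, m, 1 / sqrt(prec))
}

#' Gibbs sampler for the selection level alone
#'
#' Runs the spike-and-slab Gibbs sweep (a0, each (gamma_r, beta_r) pair,
#' tau) treating the focal log-relative abundances `a_b` as observed data
#' (the Poisson observation level is bypassed). This is the exact
#' conjugate core of the full sampler and is also useful on its own when
#' an abundance estimate is available directly.
#'
#' @param a_b length-J response vector.
#' @param X J x R standardized covariate matrix.
#' @param n_burn,n_iter,thin chain protocol.
#' @param seed integer seed; the chain is deterministic given it.
#' @param fixed_tau if non-`NULL`, tau is held at this value.
#' @param init optional [selection_state()] start.
#' @return list with matrices `gamma`, `beta` (draws x R), vectors `a0`,
#'   `tau`, of length `n_iter / thin`.
#' @export
run_selection_gibbs <- function(a_b, X, n_burn = 1000L, n_iter = 10000L,
                                thin = 10L, seed = 1L, fixed_tau = NULL,
                                init = NULL) {
  X <- as.matrix(X)
  J <- length(a_b); R <- ncol(X)
  if (nrow(X) != J) abort("X rows must match length(a_b)", "bad_dimension")
  set.seed(seed)
  st <- init %||% selection_state(gamma = rbinom(R, 1, 0.5),
                                  beta = rep(0, R), a0 = mean(a_b),
                                  tau = fixed_tau %||% 1)
  n_keep <- n_iter %/% thin
  out <- list(gamma = matrix(NA_integer_, n_keep, R,
                             dimnames = list(NULL, colnames(X))),
              beta = matrix(NA_real_, n_keep, R,
                            dimnames = list(NULL, colnames(X))),
              a0 = numeric(n_keep), tau = numeric(n_keep))
  kept <- 0L
  for (it in seq_len(n_burn + n_iter)) {
    st$a0 <- draw_a0_conditional(st, a_b, X)
    for (r in seq_len(R)) {
      pr <- gamma_full_conditional(r, st, a_b, X)
      st$gamma[r] <- rbinom(1, 1, pr)
      st$beta[r] <- draw_beta_conditional(r, st, a_b, X)
    }
    if (is.null(fixed_tau)) st$tau <- draw_tau_conditional(st, a_b, X)
    if (it > n_burn && (it - n_burn) %% thin == 0L) {
      kept <- kept + 1L
      out$gamma[kept, ] <- st$gamma
      out$beta[kept, ] <- st$beta
      out$a0[kept] <- st$a0
      out$tau[kept] <- st$tau
    }
  }
  out
}
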