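# Small fixtures built in code.

# A tiny deterministic survey: I species x J units, counts filled from a
# fixed-seed Poisson draw around ~5 per cell.
tiny_survey <- function(I = 2, J = 3, seed = 99, lambda = 5) {
  set.seed(seed)
  counts <- array(rpois(I * J * 2, lambda), c(I, J, 2),
                  dimnames = list(paste0("sp", 1:I), paste0("u", 1:J),
                                  c("dead", "alive")))
  survey_dataset(counts, surface = exp(runif(J, 0, 2)),
                 km = exp(runif(J, 0, 2)))
}

random_obs_params <- function(data, seed = 1) {
  set.seed(seed)
  I <- length(data$species); J <- length(data$units)
  p <- rnorm(I, 0, 0.4); p[1] <- 0
  observation_params(a = matrix(rnorm(I * J, 0, 0.5), I, J),
                     e_alive = rnorm(J, 0, 0.5), p_alive = p)
}

# Minimal posterior_draws-shaped object for summary-level unit tests.
fake_draws <- function(gamma_chains, covariates = NULL, units = NULL,
                       a_b_chains = NULL) {
  chains <- lapply(seq_along(gamma_chains), function(k) {
    g <- as.matrix(gamma_chains[[k]])
    list(gamma = g, beta = g * 0, a0 = numeric(nrow(g)),
         tau = rep(1, nrow(g)),
         a_b = if (is.null(a_b_chains)) NULL else as.matrix(a_b_chains[[k]]))
  })
  covariates <- covariates %||% paste0("X", seq_len(ncol(as.matrix(gamma_chains[[1]]))))
  structure(list(chains = chains, covariates = covariates,
                 units = units, species = NULL, focal = 1, reference = 2,
                 config = mcmc_config(n_chains = length(chains), n_burn = 1,
                                      n_iter = 10, thin = 1)),
            class = "posterior_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
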