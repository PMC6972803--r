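# Independent oracles, kept free of the implementation paths they check.

# Brute-force Poisson log-likelihood: term-by-term dpois over every cell.
oracle_poisson_loglik <- function(counts, lambda) {
  sum(dpois(counts, lambda, log = TRUE))
}

# Exact log marginal likelihood of y under one inclusion pattern:
# y ~ N(0, Vb * (1 1' + Xg Xg') + I / tau) with prior variance Vb on the
# intercept and every included coefficient.
oracle_log_marginal <- function(y, X, pattern, tau, prior_var = 100) {
  Xg <- cbind(1, X[, pattern == 1L, drop = FALSE])
  V <- prior_var * tcrossprod(Xg) + diag(length(y)) / tau
  ch <- chol(V)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, y, transpose = TRUE)^2))
}

# Exact posterior over all 2^R patterns (uniform Bernoulli(0.5) prior).
oracle_model_posterior <- function(y, X, tau, prior_var = 100) {
  R <- ncol(X)
  patterns <- as.matrix(expand.grid(rep(list(0:1), R)))[, R:1, drop = FALSE]
  lml <- apply(patterns, 1, function(p)
    oracle_log_marginal(y, X, p, tau, prior_var))
  w <- exp(lml - max(lml))
  data.frame(pattern = apply(patterns, 1, paste0, collapse = ""),
             prob = w / sum(w))
}

# Batch-means Monte Carlo standard error of the mean of x.
mcse_batch <- function(x, n_batch = 20) {
  n <- length(x)
  b <- floor(n / n_batch)
  m <- colMeans(matrix(x[seq_len(b * n_batch)], nrow = b))
  sd(m) / sqrt(n_batch)
}
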