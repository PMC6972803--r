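## Posterior summaries: inclusion probabilities, model table, final refit
## with credible intervals, and the [0,1] relative abundance index.

pool_gamma <- function(draws) {
  do.call(rbind, lapply(draws$chains, function(ch) ch$gamma))
}

#' Posterior inclusion probabilities
#'
#' `p_r` is the fraction of retained draws (chains pooled) in which
#' covariate `r` is in the model (`gamma_r = 1`).
#'
#' @param draws a `posterior_draws` object.
#' @return data frame with columns `covariate`, `p` and `rank` (1 =
#'   highest `p_r`), sorted by rank; class `inclusion_summary`.
#' @export
inclusion_probabilities <- function(draws) {
  g <- pool_gamma(draws)
  if (is.null(g) || nrow(g) == 0L) abort("no retained draws", "empty_draws")
  p <- colMeans(g)
  out <- data.frame(covariate = draws$covariates %||% colnames(g) %||%
                      paste0("X", seq_along(p)),
                    p = as.numeric(p))
  out <- out[order(-out$p), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("inclusion_summary", "data.frame")
  out
}

#' Posterior model probabilities
#'
#' Frequency of every visited inclusion pattern `(gamma_1, ..., gamma_R)`
#' among the pooled retained draws, sorted descending. Probabilities sum
#' to one; only visited patterns appear.
#'
#' @param draws a `posterior_draws` object.
#' @return data frame with columns `pattern` (R-bit string), `model`
#'   (covariate names joined by ` + `, or `(intercept only)`) and
#'   `probability`.
#' @export
model_probabilities <- function(draws) {
  g <- pool_gamma(draws)
  if (is.null(g) || nrow(g) == 0L) abort("no retained draws", "empty_draws")
  pat <- apply(g, 1, paste0, collapse = "")
  tab <- sort(table(pat), decreasing = TRUE)
  labs <- vapply(names(tab), function(p) {
    on <- strsplit(p, "")[[1]] == "1"
    if (!any(on)) "(intercept only)" else
      paste(draws$covariates[on], collapse = " + ")
  }, character(1))
  data.frame(pattern = names(tab), model = unname(labs),
             probability = as.numeric(tab) / length(pat),
             row.names = NULL)
}

#' Select covariates and refit the final model
#'
#' Retains the covariates with `p_r > threshold` (strict inequality,
#' default 0.5), then reruns the sampler with the inclusion indicators
#' frozen (selected = 1, others = 0, no indicator updates) and reports
#' posterior means and central 95% credible intervals (2.5 / 97.5
#' percentiles) of the retained coefficients. If nothing is selected the
#' refit is intercept-only.
#'
#' @param draws a `posterior_draws` object from [run_mcmc()].
#' @param data,X the survey and covariate matrix used for `draws`.
#' @param threshold inclusion threshold on `p_r`.
#' @param config an [mcmc_config()] for the refit; defaults to the one
#'   stored in `draws` (with a shifted seed so the refit chain is
#'   independent).
#' @return an object of class `final_fit`: list with `selected`,
#'   `coefficients` (data frame: covariate, mean, lower, upper), `a0`,
#'   `tau` summaries and the refit `posterior_draws`.
#' @export
select_and_refit <- function(draws, data, X, threshold = 0.5,
                             config = NULL) {
  inc <- inclusion_probabilities(draws)
  sel <- inc$covariate[inc$p > threshold]
  gfix <- as.integer(draws$covariates %in% sel)
  ## with the indicators frozen the selection layer is conjugate, so the
  ## extra block iterations used for indicator mixing are unnecessary
  config <- config %||% utils::modifyList(
    draws$config,
    list(seed = draws$config$seed + 1000L, pair_sweeps = 1L,
         focal_sweeps = 1L))
  class(config) <- "mcmc_config"
  refit <- run_mcmc(data, X, config, gamma_fixed = gfix)
  beta <- do.call(rbind, lapply(refit$chains, function(ch) ch$beta))
  a0 <- unlist(lapply(refit$chains, function(ch) ch$a0))
  tau <- unlist(lapply(refit$chains, function(ch) ch$tau))
  coefs <- data.frame(covariate = character(0), mean = numeric(0),
                      lower = numeric(0), upper = numeric(0))
  if (length(sel)) {
    bsel <- beta[, sel, drop = FALSE]
    coefs <- data.frame(covariate = sel,
                        mean = colMeans(bsel),
                        lower = apply(bsel, 2, quantile, 0.025),
                        upper = apply(bsel, 2, quantile, 0.975),
                        row.names = NULL)
  }
  structure(list(selected = sel, threshold = threshold,
                 coefficients = coefs,
                 a0 = c(mean = mean(a0),
                        lower = unname(quantile(a0, 0.025)),
                        upper = unname(quantile(a0, 0.975))),
                 tau = c(mean = mean(tau),
                         lower = unname(quantile(tau, 0.025)),
                         upper = unname(quantile(tau, 0.975))),
                 draws = refit),
            class = "final_fit")
}

#' @export
print.final_fit <- function(x, ...) {
  cat("Final model (p_r >", x$threshold, "):",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(intercept only)", "\n")
  if (nrow(x$coefficients)) {
    df <- x$coefficients
    df$mean <- round(df$mean, 3)
    df$lower <- round(df$lower, 3)
    df$upper <- round(df$upper, 3)
    print(df, row.names = FALSE)
  }
  cat(sprintf("a0 = %.3f; tau = %.2f\n", x$a0[["mean"]], x$tau[["mean"]]))
  invisible(x)
}

#' Relative abundance index on [0, 1]
#'
#' Min-max rescaling of the per-unit posterior means of the focal
#' species' log-relative abundance: `index_j = (m_j - min m) /
#' (max m - min m)`. Invariant to increasing affine transforms of the
#' posterior means; the least and most abundant units map to exactly 0
#' and 1.
#'
#' @param x a `posterior_draws` or `final_fit` object.
#' @return data frame with columns `unit_id`, `a_b_mean`, `index`.
#' @export
abundance_index <- function(x) {
  if (inherits(x, "final_fit")) x <- x$draws
  stopifnot(inherits(x, "posterior_draws"))
  m <- colMeans(do.call(rbind, lapply(x$chains, function(ch) ch$a_b)))
  rng <- range(m)
  if (diff(rng) <= 0)
    abort("all posterior means equal; index undefined", "degenerate_range")
  data.frame(unit_id = x$units, a_b_mean = as.numeric(m),
             index = (m - rng[1]) / diff(rng), row.names = NULL)
}
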