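## User-facing fitting function and methods.

#' Fit the effort-corrected abundance model with covariate selection
#'
#' One-call interface to the whole analysis: runs the Metropolis-within-
#' Gibbs sampler on a survey, checks cross-chain agreement of the
#' inclusion probabilities, selects the covariates with `p_r >
#' threshold`, refits the final model with the selection frozen, and
#' computes the `[0, 1]` relative abundance index.
#'
#' @param data a [survey_dataset()].
#' @param X J x R standardized covariate matrix (see
#'   [standardize_columns()]).
#' @param config an [mcmc_config()]; default the scaled-down test
#'   profile.
#' @param threshold posterior inclusion probability cut for the final
#'   model (strict; default 0.5).
#' @param focal,reference focal / reference species (index or name);
#'   override `config`.
#' @param agreement_tol tolerance of the cross-chain mixing check.
#' @return an object of class `abundsel` with components `draws`,
#'   `inclusion`, `models`, `agreement`, `final`, `index`.
#' @examples
#' spec <- scenario_spec(J = 40, I = 3, R = 3, active_set = 1,
#'                       true_beta = 0.5, seed = 42)
#' sim <- simulate_survey(spec)
#' fit <- abundsel(sim$data, sim$X,
#'                 config = mcmc_profile("test", n_chains = 2,
#'                                       n_burn = 200, n_iter = 1000,
#'                                       thin = 5))
#' coef(fit)
#' @export
abundsel <- function(data, X, config = mcmc_profile("test"),
                     threshold = 0.5, focal = NULL, reference = NULL,
                     agreement_tol = 0.05) {
  if (!is.null(focal)) config$focal_species <- focal
  if (!is.null(reference)) config$reference_species <- reference
  draws <- run_mcmc(data, X, config)
  agreement <- if (length(draws$chains) >= 2L)
    check_chain_agreement(draws, tol = agreement_tol) else NULL
  if (!is.null(agreement) && !agreement$pass)
    warning("cross-chain inclusion probabilities disagree beyond ",
            agreement_tol, "; consider longer chains", call. = FALSE)
  final <- select_and_refit(draws, data, X, threshold = threshold)
  structure(list(draws = draws,
                 inclusion = inclusion_probabilities(draws),
                 models = model_probabilities(draws),
                 agreement = agreement,
                 final = final,
                 index = abundance_index(final),
                 threshold = threshold,
                 call = match.call()),
            class = "abundsel")
}

#' @export
print.abundsel <- function(x, ...) {
  cat("Effort-corrected abundance model with spike-and-slab selection\n")
  cat("Posterior inclusion probabilities:\n")
  inc <- x$inclusion
  inc$p <- round(inc$p, 3)
  print(utils::head(inc, 8), row.names = FALSE)
  cat("\n")
  print(x$final)
  invisible(x)
}

#' @export
summary.abundsel <- function(object, ...) {
  cat("Chains:", length(object$draws$chains),
      " retained draws/chain:", nrow(object$draws$chains[[1]]$gamma), "\n")
  if (!is.null(object$agreement))
    cat("Cross-chain max |p_r| difference:",
        signif(max(object$agreement$max_diff), 3),
        if (object$agreement$pass) "(pass)" else "(FAIL)", "\n")
  cat("Top models:\n")
  print(utils::head(object$models[c("model", "probability")], 5),
        row.names = FALSE)
  cat("\n")
  print(object$final)
  acc <- colMeans(do.call(rbind,
                          lapply(object$draws$chains, function(ch) ch$accept)))
  cat("Metropolis acceptance rates:",
      paste(names(acc), signif(acc, 2), collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.abundsel <- function(object, ...) {
  setNames(object$final$coefficients$mean,
           object$final$coefficients$covariate)
}

#' @importFrom graphics barplot abline par
#' @export
plot.abundsel <- function(x, which = c("inclusion", "index"), ...) {
  which <- match.arg(which)
  if (which == "inclusion") {
    barplot(x$inclusion$p, names.arg = x$inclusion$covariate, las = 2,
            ylab = "posterior inclusion probability", ylim = c(0, 1), ...)
    abline(h = x$threshold, lty = 2)
  } else {
    barplot(sort(x$index$index), ylab = "relative abundance index",
            xlab = "units (sorted)", border = NA, ...)
  }
  invisible(x)
}
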