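## Observation level: Poisson log-linear model of detections,
## log lambda_ijk = s_j + a_ij + e_jk + p_ik, in the identifiable
## parametrization (p_i,dead = 0 for all species, p_ref,k = 0, and
## e_j,dead anchored to log V_j).

#' Identifiable observation-level parameters
#'
#' Holds the free parameters of the Poisson detection model. Fixed
#' conventions: the log-effort for dead animals is `log(V_j)` (any
#' proportionality constant is absorbed into the relative abundances
#' `a_ij`), detectability offsets are zero for the dead status and for the
#' reference species, so all remaining parameters are identifiable.
#'
#' @param a I x J matrix of log-relative abundances `a_ij`.
#' @param e_alive length-J vector `e_j2`, log-effort for alive detections.
#' @param p_alive length-I vector `p_i2`, alive-status detectability
#'   offsets; the entry for the reference species must be 0.
#' @param reference index of the reference species (default 1).
#' @param e_dead optional length-J vector overriding the `log(V_j)` anchor
#'   (used when converting from a natural parametrization).
#' @return an object of class `observation_params`.
#' @export
observation_params <- function(a, e_alive, p_alive, reference = 1L,
                               e_dead = NULL) {
  a <- as.matrix(a)
  I <- nrow(a); J <- ncol(a)
  if (length(e_alive) != J || length(p_alive) != I)
    abort("dimension mismatch between a, e_alive, p_alive", "bad_dimension")
  if (!is.null(e_dead) && length(e_dead) != J)
    abort("e_dead length must be J", "bad_dimension")
  if (abs(p_alive[reference]) > 1e-12)
    abort("p_alive must be 0 for the reference species", "schema")
  if (!all(is.finite(a)) || !all(is.finite(e_alive)) || !all(is.finite(p_alive)))
    abort("non-finite parameter", "schema")
  structure(list(a = a, e_alive = as.numeric(e_alive),
                 p_alive = as.numeric(p_alive),
                 reference = as.integer(reference),
                 e_dead = if (is.null(e_dead)) NULL else as.numeric(e_dead)),
            class = "observation_params")
}

#' Log intensity of every survey cell
#'
#' Computes `log lambda_ijk = s_j + a_ij + e_jk + p_ik` with
#' `s_j = log(surface_j)`, `e_j1 = log(km_j)` (or the `e_dead` override),
#' `p_i1 = 0`.
#'
#' @param params an [observation_params()] object.
#' @param data a [survey_dataset()].
#' @return numeric I x J x 2 array of log intensities.
#' @export
compute_log_intensity <- function(params, data) {
  I <- nrow(params$a); J <- ncol(params$a)
  if (I != length(data$species) || J != length(data$units))
    abort("params/data dimension mismatch", "bad_dimension")
  if (is.null(params$e_dead) && any(data$km == 0))
    abort("zero-km unit present; drop it or supply e_dead", "zero_effort_unit")
  s <- log(data$surface)
  e_dead <- params$e_dead %||% log(data$km)
  out <- array(NA_real_, c(I, J, 2L),
               dimnames = dimnames(data$counts))
  base <- params$a + matrix(s, I, J, byrow = TRUE)
  out[, , 1L] <- base + matrix(e_dead, I, J, byrow = TRUE)
  out[, , 2L] <- base + matrix(params$e_alive, I, J, byrow = TRUE) +
    params$p_alive
  out
}

#' Poisson log-likelihood of a survey
#'
#' `sum_ijk [ N_ijk * log(lambda_ijk) - lambda_ijk - log(N_ijk!) ]`,
#' accumulated in double precision with `lgamma` for the factorial term.
#'
#' @inheritParams compute_log_intensity
#' @return a finite scalar for finite parameters.
#' @export
survey_log_likelihood <- function(params, data) {
  ll <- compute_log_intensity(params, data)
  N <- data$counts
  sum(N * ll - exp(ll) - lgamma(N + 1))
}

#' Convert natural-scale parameters to the identifiable parametrization
#'
#' The natural factorization `lambda_ijk = S_j A_ij E_jk P_ik` (true
#' density, effort, detection probability) is over-parametrized; this maps
#' it to the identifiable log-scale parameters via
#' `a_ij = log(beta) + log(P_i1) + log(A_ij)`,
#' `e_jk = log(E_jk / beta) + log(P_1k / P_11)`,
#' `p_ik = log(P_ik / P_1k) + log(P_11 / P_i1)`,
#' which leaves the Poisson likelihood unchanged and zeroes `p_i1` and
#' `p_1k` by construction.
#'
#' @param nat list with `A` (I x J density matrix, > 0), `E` (J x 2 effort
#'   matrix, > 0), `P` (I x 2 detection probabilities in (0, 1]) and
#'   `beta_const` (> 0, the dead-effort proportionality constant).
#' @param data a [survey_dataset()] (supplies dimensions and labels).
#' @return an [observation_params()] with `e_dead` set from `E`.
#' @export
natural_to_reduced <- function(nat, data) {
  A <- as.matrix(nat$A); E <- as.matrix(nat$E); P <- as.matrix(nat$P)
  b <- nat$beta_const
  if (any(A <= 0) || any(E <= 0) || any(P <= 0) || any(P > 1) || b <= 0)
    abort("natural parameters must be strictly positive (P in (0,1])",
          "non_positive_param")
  I <- nrow(A); J <- ncol(A)
  if (nrow(P) != I || ncol(P) != 2L || nrow(E) != J || ncol(E) != 2L)
    abort("natural parameter dimension mismatch", "bad_dimension")
  a <- log(b) + matrix(log(P[, 1L]), I, J) + log(A)
  e <- sweep(log(E / b), 2L, log(P[1L, ] / P[1L, 1L]), `+`)
  p <- log(P / P[rep(1L, I), ]) + log(P[1L, 1L] / P[, 1L])
  stopifnot(max(abs(p[, 1L])) < 1e-12, abs(p[1L, 2L]) < 1e-12)
  observation_params(a, e_alive = e[, 2L], p_alive = p[, 2L],
                     reference = 1L, e_dead = e[, 1L])
}
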