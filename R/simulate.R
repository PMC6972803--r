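## Synthetic survey generator: forward simulation of the two-level model
## with known ground truth, for recovery and calibration tests.

#' Scenario specification for the synthetic survey generator
#'
#' Describes a multi-species roadside survey: `J` spatial units, `I`
#' species (one focal), `R` standardized covariates, a sparse set of true
#' covariate effects on the focal species' log-relative abundance, and
#' the distributions of the nuisance parameters and effort.
#'
#' Defaults emulate a national-scale roadside registry: kilometres
#' travelled per unit are log-normal(meanlog 11, sdlog 0.7), unit surface
#' areas log-normal(meanlog 6.6, sdlog 0.8) (mean around 10^2.9 km^2),
#' alive-detection effort correlated with but distinct from kilometres
#' (`e_j2 ~ N(log V_j - 1, sd 0.3)`), non-focal species' log-relative
#' abundances scattered (sd 0.5) around the focal baseline `true_a0`, and
#' alive-status detectability offsets `p_i2 ~ N(0, sd 0.5)` for non-
#' reference species. `true_a0 = -15.5` puts the focal species at roughly
#' ten detections per unit under those effort scales.
#'
#' @param J,I,R number of units, species (>= 2), covariates.
#' @param covariate_correlation common pairwise correlation of the
#'   covariate draw, in `[0, 1)`.
#' @param active_set integer indices (in `1..R`) of covariates with a true
#'   effect.
#' @param true_beta effects for `active_set`, same length.
#' @param true_a0 intercept of the focal log-abundance regression.
#' @param true_tau precision of the focal log-abundance noise.
#' @param focal,reference species indices; defaults 2 and 1 (the
#'   reference species must differ from the focal one so that the
#'   reference detectability constraint does not touch the focal row).
#' @param a_nuisance_sd,e_alive_offset,e_alive_sd,p_alive_sd location and
#'   spread of the nuisance parameters (see Details).
#' @param effort_meanlog,effort_sdlog,surface_meanlog,surface_sdlog
#'   log-normal parameters of `V_j` and `S_j`.
#' @param seed integer; all randomness derives from it through fixed
#'   per-component sub-seeds, so e.g. the covariate draw does not depend
#'   on `I`.
#' @return an object of class `scenario_spec` (a validated list).
#' @export
scenario_spec <- function(J = 200L, I = 6L, R = 13L,
                          covariate_correlation = 0.2,
                          active_set = integer(0), true_beta = numeric(0),
                          true_a0 = -15.5, true_tau = 25,
                          focal = 2L, reference = 1L,
                          a_nuisance_sd = 0.5, e_alive_offset = -1,
                          e_alive_sd = 0.3, p_alive_sd = 0.5,
                          effort_meanlog = 11, effort_sdlog = 0.7,
                          surface_meanlog = 6.6, surface_sdlog = 0.8,
                          seed = 1L) {
  if (J < 2 || I < 2 || R < 1) abort("J, I >= 2 and R >= 1 required", "bad_dimension")
  if (covariate_correlation < 0 || covariate_correlation >= 1)
    abort("covariate_correlation must be in [0, 1)", "schema")
  if (length(active_set) != length(true_beta))
    abort("active_set and true_beta lengths differ", "bad_dimension")
  if (length(active_set) && (any(active_set < 1) || any(active_set > R)))
    abort("active_set indices out of 1..R", "bad_index")
  if (true_tau < TAU_LO || true_tau > TAU_HI)
    abort("true_tau outside [0.0001, 1000]", "schema")
  if (focal == reference) abort("focal and reference species must differ", "schema")
  structure(as.list(environment()), class = "scenario_spec")
}

#' Preset scenarios
#'
#' `"lowland"` reproduces the structure of a lowland national survey:
#' `J = 500` units, `I = 6` mustelid-like species, `R = 13` environmental
#' covariates of which four act on the focal species with effects
#' `0.461, 0.400, 0.541, -0.407` (food-resource and forest-fragmentation
#' style covariates), noise precision `tau = 25`.
#'
#' @param name preset name; currently `"lowland"`.
#' @param ... overrides passed to [scenario_spec()].
#' @return a `scenario_spec`.
#' @export
scenario_preset <- function(name = "lowland", ...) {
  name <- match.arg(name)
  defaults <- list(J = 500L, I = 6L, R = 13L,
                   covariate_correlation = 0.2,
                   active_set = 1:4,
                   true_beta = c(0.461, 0.400, 0.541, -0.407),
                   true_tau = 25)
  do.call(scenario_spec, utils::modifyList(defaults, list(...)))
}

## Fixed sub-seed offsets; changing one component's dimensions leaves the
## other components' draws untouched.
sub_seed <- function(seed, component) {
  (as.integer(seed) + 1000L * match(component,
    c("covariates", "effort", "nuisance", "focal", "counts"))) %% .Machine$integer.max
}

#' Generate an equicorrelated standardized covariate matrix
#'
#' Draws `J` rows from a Gaussian with common pairwise correlation, then
#' standardizes every column (mean 0, sample sd 1). Deterministic given
#' `seed`.
#'
#' @param J,R dimensions (`J > R >= 1`).
#' @param correlation common pairwise correlation in `[0, 1)`.
#' @param seed integer seed.
#' @param labels optional column labels (default `X1..XR`).
#' @return a `covariate_matrix` (J x R).
#' @export
generate_covariates <- function(J, R, correlation = 0, seed = 1L,
                                labels = paste0("X", seq_len(R))) {
  if (R < 1 || J <= R) abort("need J > R >= 1", "bad_dimension")
  if (correlation < 0 || correlation >= 1)
    abort("correlation must be in [0, 1)", "schema")
  set.seed(seed)
  Z <- matrix(rnorm(J * R), J, R)
  common <- rnorm(J)
  raw <- sqrt(1 - correlation) * Z + sqrt(correlation) * common
  tab <- data.frame(unit_id = paste0("u", seq_len(J)))
  tab[labels] <- as.data.frame(raw)
  standardize_columns(tab, labels)
}

#' Simulate a survey from a scenario
#'
#' Forward-simulates the full two-level model: the focal species' log-
#' relative abundance is `a_bj ~ N(a0 + sum_active beta_r X_jr, tau)`
#' (tau a precision); counts are
#' `N_ijk ~ Poisson(exp(s_j + a_ij + e_jk + p_ik))` with `s_j = log S_j`,
#' `e_j1 = log V_j`, `p_i1 = 0` and `p_ref,2 = 0`. Returns the dataset
#' together with the generating parameters for recovery tests.
#'
#' @param spec a [scenario_spec()].
#' @param X optional `covariate_matrix` (J x R); generated from the spec
#'   when omitted.
#' @return `list(data, X, truth)` where `truth` holds the
#'   [observation_params()] and [selection_state()] used, plus `a_b` and
#'   the focal/reference indices.
#' @export
simulate_survey <- function(spec, X = NULL) {
  J <- spec$J; I <- spec$I; R <- spec$R
  if (is.null(X))
    X <- generate_covariates(J, R, spec$covariate_correlation,
                             seed = sub_seed(spec$seed, "covariates"))
  X <- as.matrix(X)
  if (nrow(X) != J || ncol(X) != R)
    abort("X dimensions do not match spec", "bad_dimension")

  set.seed(sub_seed(spec$seed, "effort"))
  V <- rlnorm(J, spec$effort_meanlog, spec$effort_sdlog)
  S <- rlnorm(J, spec$surface_meanlog, spec$surface_sdlog)

  set.seed(sub_seed(spec$seed, "nuisance"))
  a <- matrix(rnorm(I * J, spec$true_a0, spec$a_nuisance_sd), I, J)
  e_alive <- rnorm(J, log(V) + spec$e_alive_offset, spec$e_alive_sd)
  p_alive <- rnorm(I, 0, spec$p_alive_sd)
  p_alive[spec$reference] <- 0

  gamma <- integer(R); gamma[spec$active_set] <- 1L
  beta <- numeric(R); beta[spec$active_set] <- spec$true_beta
  state <- selection_state(gamma, beta, a0 = spec$true_a0, tau = spec$true_tau)

  set.seed(sub_seed(spec$seed, "focal"))
  mu <- regression_mean(state, X)
  a_b <- rnorm(J, mu, 1 / sqrt(spec$true_tau))
  a[spec$focal, ] <- a_b

  params <- observation_params(a, e_alive, p_alive, reference = spec$reference)
  units <- rownames(X) %||% paste0("u", seq_len(J))
  species <- paste0("sp", seq_len(I))
  species[spec$focal] <- "focal"
  counts <- array(0L, c(I, J, 2L),
                  dimnames = list(species, units, STATUS_LEVELS))
  data_shell <- survey_dataset(counts, surface = S, km = V)
  lam <- exp(compute_log_intensity(params, data_shell))

  set.seed(sub_seed(spec$seed, "counts"))
  counts[] <- rpois(length(lam), lam)
  data <- survey_dataset(counts, surface = S, km = V)
  list(data = data, X = X,
       truth = list(params = params, state = state, a_b = a_b,
                    focal = spec$focal, reference = spec$reference))
}
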