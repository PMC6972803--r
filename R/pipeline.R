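## End-to-end pipeline and draw serialization.

#' Serialize / restore posterior draws
#'
#' Writes one CSV per chain (`chain_1.csv`, ... with one column per
#' retained parameter, named `gamma.<cov>`, `beta.<cov>`, `a0`, `tau`,
#' `a_b.<unit>`, `e_alive.<unit>`, `p_alive.<species>`, plus the
#' iteration index) and a JSON manifest holding the configuration,
#' labels and acceptance rates.
#'
#' @param draws a `posterior_draws` object.
#' @param dir output directory (created if needed).
#' @return `write_posterior_draws`: `dir` invisibly;
#'   `read_posterior_draws`: a `posterior_draws` object.
#' @export
write_posterior_draws <- function(draws, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  thin <- draws$config$thin
  for (ch in seq_along(draws$chains)) {
    d <- draws$chains[[ch]]
    df <- data.frame(iteration = seq_len(nrow(d$gamma)) * thin)
    add <- function(m, prefix) {
      m <- as.matrix(m)
      colnames(m) <- paste0(prefix, ".", colnames(m))
      cbind(df, as.data.frame(m))
    }
    df <- add(d$gamma, "gamma"); df <- add(d$beta, "beta")
    df$a0 <- d$a0; df$tau <- d$tau
    df <- add(d$a_b, "a_b"); df <- add(d$e_alive, "e_alive")
    df <- add(d$p_alive, "p_alive")
    write.csv(df, file.path(dir, sprintf("chain_%d.csv", ch)),
              row.names = FALSE)
  }
  manifest <- list(
    n_chains = length(draws$chains),
    covariates = draws$covariates, units = draws$units,
    species = draws$species, focal = draws$focal,
    reference = draws$reference,
    config = unclass(draws$config)[c("n_chains", "n_burn", "n_iter", "thin",
                                     "seed", "proposal_sd", "adapt")],
    accept = lapply(draws$chains, function(d) as.list(d$accept)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_posterior_draws
#' @export
read_posterior_draws <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  take <- function(df, prefix, labels) {
    m <- as.matrix(df[paste0(prefix, ".", labels)])
    colnames(m) <- labels
    m
  }
  chains <- lapply(seq_len(mf$n_chains), function(ch) {
    df <- read.csv(file.path(dir, sprintf("chain_%d.csv", ch)),
                   check.names = FALSE)
    list(gamma = take(df, "gamma", mf$covariates),
         beta = take(df, "beta", mf$covariates),
         a0 = df$a0, tau = df$tau,
         a_b = take(df, "a_b", mf$units),
         e_alive = take(df, "e_alive", mf$units),
         p_alive = take(df, "p_alive", mf$species),
         accept = unlist(mf$accept[[ch]]))
  })
  cfg <- do.call(mcmc_config, as.list(mf$config))
  structure(list(chains = chains, covariates = mf$covariates,
                 units = mf$units, species = mf$species,
                 focal = mf$focal, reference = mf$reference, config = cfg),
            class = "posterior_draws")
}

summaries_to_csv <- function(draws, data, X, threshold, outdir, prefix = "") {
  final <- select_and_refit(draws, data, X, threshold = threshold)
  inc <- inclusion_probabilities(draws)
  tab2 <- merge(inc, final$coefficients, by = "covariate", all.x = TRUE,
                sort = FALSE)
  tab2 <- tab2[order(-tab2$p), c("covariate", "p", "mean", "lower", "upper")]
  paths <- c(inclusion = paste0(prefix, "inclusion.csv"),
             models = paste0(prefix, "models.csv"),
             index = paste0(prefix, "index.csv"))
  write.csv(tab2, file.path(outdir, paths["inclusion"]), row.names = FALSE)
  write.csv(model_probabilities(draws), file.path(outdir, paths["models"]),
            row.names = FALSE)
  write.csv(abundance_index(final), file.path(outdir, paths["index"]),
            row.names = FALSE)
  list(final = final, files = unname(paths))
}

#' Run the full analysis pipeline
#'
#' Reads the survey and covariate CSVs, standardizes the covariates
#' (applying the monthly-climate PCA when the 24 monthly columns are
#' present), optionally splits units into lowland/mountain strata by mean
#' elevation, fits the model per stratum, checks cross-chain agreement,
#' and writes inclusion/model/index CSVs, the per-chain draw CSVs and a
#' JSON run log (seed, versions, warnings, file manifest with row counts
#' and checksums) to the output directory.
#'
#' @param config a named list or path to a JSON file with entries:
#'   `counts`, `effort`, `covariates` (CSV paths), `outdir`; optional
#'   `covariate_columns`, `focal`, `reference`, `threshold` (inclusion
#'   cut, default 0.5), `elevation_threshold_m` (default 400; the split
#'   runs only if the covariate table has `mean_elevation`), `split`
#'   (logical override), `mcmc` (list of [mcmc_config()] overrides),
#'   `profile` (`"test"` or `"paper"`), `seed`.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste("config not found:", config), "schema")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (f in c("counts", "effort", "covariates"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      abort(paste("missing input file for", f), "schema")
  outdir <- config$outdir %||% "abundsel-output"
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  warns <- character(0)
  wh <- function(w) { warns <<- c(warns, conditionMessage(w))
                      invokeRestart("muffleWarning") }

  data <- read_survey_tables(config$counts, config$effort)
  tab <- read_covariate_table(config$covariates)
  if (!identical(as.character(tab$unit_id), data$units))
    tab <- tab[match(data$units, as.character(tab$unit_id)), , drop = FALSE]
  if (anyNA(tab$unit_id))
    abort("covariate table does not cover all survey units", "unit_mismatch")

  clim <- c(paste0("temp_", 1:12), paste0("rain_", 1:12))
  has_clim <- all(clim %in% names(tab))
  cols <- config$covariate_columns %||%
    setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
            c("unit_id", "mean_elevation", if (has_clim) clim))
  X <- standardize_columns(tab, cols)
  if (has_clim) {
    pcs <- climate_pca(tab)
    X <- structure(cbind(X, standardize_columns(
      data.frame(unit_id = rownames(pcs), unclass(pcs)))),
      class = class(X))
  }

  cfg <- do.call(mcmc_profile,
                 c(list(name = config$profile %||% "test",
                        seed = as.integer(config$seed %||% 1L),
                        focal_species = config$focal,
                        reference_species = config$reference),
                   config$mcmc))
  threshold <- config$threshold %||% 0.5

  do_split <- config$split %||% ("mean_elevation" %in% names(tab))
  groups <- if (isTRUE(do_split)) {
    split_ids <- split_by_elevation(tab, config$elevation_threshold_m %||% 400)
    Filter(function(g) length(g) > 0, split_ids)
  } else list(all = data$units)

  log <- list(package = "abundsel",
              version = as.character(utils::packageVersion("abundsel")),
              r_version = as.character(getRversion()),
              seed = cfg$seed, threshold = threshold,
              groups = lapply(groups, length), files = list())
  for (g in names(groups)) {
    ids <- groups[[g]]
    keep <- data$units %in% ids
    dsub <- survey_dataset(data$counts[, keep, , drop = FALSE],
                           data$surface[keep], data$km[keep])
    Xsub <- X[keep, , drop = FALSE]
    prefix <- if (length(groups) > 1) paste0(g, "_") else ""
    res <- withCallingHandlers({
      draws <- run_mcmc(dsub, Xsub, cfg)
      agree <- if (cfg$n_chains >= 2) check_chain_agreement(draws) else NULL
      write_posterior_draws(draws, file.path(outdir, paste0(prefix, "draws")))
      s <- summaries_to_csv(draws, dsub, Xsub, threshold, outdir, prefix)
      list(agree = agree, files = s$files)
    }, warning = wh)
    log$files <- c(log$files, res$files)
    if (!is.null(res$agree))
      log[[paste0(g, "_max_chain_disagreement")]] <- max(res$agree$max_diff)
  }
  write_covariate_matrix(X, file.path(outdir, "covariates_standardized.csv"))
  log$files <- c(log$files, "covariates_standardized.csv")
  log$warnings <- warns
  log$manifest <- lapply(log$files, function(f) {
    p <- file.path(outdir, f)
    list(name = f, rows = length(readLines(p)) - 1L,
         md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(log, file.path(outdir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
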