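Package: abundsel
Title: Effort-Corrected Relative Abundance with Bayesian Covariate Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-level hierarchical Bayesian analysis of multi-species
    count surveys. The observation level is a Poisson log-linear model of
    detections per spatial unit, species and status (dead or alive), with
    detection effort for dead animals anchored to kilometres travelled, so
    that the log-relative abundance of every species is identifiable. The
    second level regresses the focal species' log-relative abundance on
    standardized environmental covariates using Kuo-Mallick spike-and-slab
    indicator variable selection, fitted by Metropolis-within-Gibbs MCMC.
    Includes covariate preparation (standardization, climate PCA, elevation
    stratification), a synthetic survey generator with known ground truth,
    posterior summaries (inclusion probabilities, model table, final refit
    with credible intervals, a [0,1] relative abundance index), and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
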