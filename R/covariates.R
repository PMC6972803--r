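## Covariate preparation: standardization, climate PCA, elevation strata.

#' Standardize covariate columns to mean 0, standard deviation 1
#'
#' Converts named columns of a per-unit covariate table into the
#' standardized predictor matrix \eqn{X_{jr}} used by the regression level.
#' Standardization uses the sample standard deviation (denominator
#' \eqn{J - 1}) so effect sizes are comparable across covariates.
#'
#' @param table a data frame with one row per spatial unit; its first
#'   column (or a column named `unit_id`) identifies the unit.
#' @param columns character vector of column names to standardize; default
#'   all numeric columns except `unit_id`.
#' @return a numeric J x R matrix of class `covariate_matrix`, with
#'   `rownames` the unit ids and `colnames` the covariate labels. Every
#'   column has mean 0 and sample sd 1.
#' @examples
#' tab <- data.frame(unit_id = 1:3, x = c(2, 4, 6))
#' standardize_columns(tab, "x")   # -1, 0, 1
#' @export
standardize_columns <- function(table, columns = NULL) {
  ids <- covariate_unit_ids(table)
  if (is.null(columns)) {
    columns <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                       "unit_id")
  }
  missing <- setdiff(columns, names(table))
  if (length(missing))
    abort(paste("missing column(s):", paste(missing, collapse = ", ")),
          "missing_column")
  X <- matrix(NA_real_, nrow(table), length(columns),
              dimnames = list(ids, columns))
  for (cc in columns) {
    v <- table[[cc]]
    if (anyNA(v)) abort(paste("missing values in column", cc), "missing_value")
    s <- sd(v)
    if (!is.finite(s) || s == 0)
      abort(paste("column", cc, "has zero variance"), "constant_column")
    X[, cc] <- (v - mean(v)) / s
  }
  structure(X, class = c("covariate_matrix", class(X)))
}

covariate_unit_ids <- function(table) {
  ids <- if ("unit_id" %in% names(table)) table[["unit_id"]] else table[[1L]]
  if (anyDuplicated(ids)) abort("duplicated unit ids", "schema")
  as.character(ids)
}

#' Principal component scores of monthly climate variables
#'
#' Reduces the 24 monthly climate columns (12 mean temperatures, 12
#' rainfall totals) to a few principal components of their correlation
#' matrix. By default the columns are those named `temp_1` ... `temp_12`
#' and `rain_1` ... `rain_12`, and the first three components are kept.
#' Each component's sign is fixed so that the largest-magnitude loading is
#' positive, making scores reproducible across platforms.
#'
#' @param table per-unit covariate table (see [standardize_columns()]).
#' @param n_components number of leading components to keep.
#' @param columns names of the climate columns; default the 24 monthly
#'   temperature/rainfall columns.
#' @return a `covariate_matrix` of unit scores (J x `n_components`) with
#'   columns `PC1`, `PC2`, ...; attribute `explained_variance` holds the
#'   fraction of total (correlation-scale) variance carried by every
#'   component of the full decomposition.
#' @export
climate_pca <- function(table, n_components = 3L,
                        columns = c(paste0("temp_", 1:12),
                                    paste0("rain_", 1:12))) {
  ids <- covariate_unit_ids(table)
  missing <- setdiff(columns, names(table))
  if (length(missing))
    abort(paste("missing climate column(s):", paste(missing, collapse = ", ")),
          "missing_column")
  M <- as.matrix(table[columns])
  if (anyNA(M)) abort("missing values in climate columns", "missing_value")
  sds <- apply(M, 2, sd)
  if (any(sds == 0))
    abort(paste("constant climate column(s):",
                paste(columns[sds == 0], collapse = ", ")), "constant_column")
  if (n_components > ncol(M)) abort("n_components exceeds column count", "bad_dimension")
  pc <- prcomp(M, center = TRUE, scale. = TRUE)
  ## sign convention: largest |loading| per axis is positive
  for (k in seq_len(ncol(pc$rotation))) {
    l <- pc$rotation[, k]
    if (l[which.max(abs(l))] < 0) {
      pc$rotation[, k] <- -l
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  dimnames(scores) <- list(ids, paste0("PC", seq_len(n_components)))
  structure(scores,
            class = c("covariate_matrix", class(scores)),
            explained_variance = ev,
            loadings = pc$rotation)
}

#' Split units into lowland and mountain strata by mean elevation
#'
#' Units with mean elevation strictly below the threshold are "lowland",
#' all others "mountain" (a unit exactly at the threshold is mountain).
#'
#' @param table per-unit covariate table containing a `mean_elevation`
#'   column in metres a.s.l.
#' @param threshold_m elevation cut in metres (default 400).
#' @return `list(lowland = <unit ids>, mountain = <unit ids>)`, a disjoint
#'   exhaustive partition of the units.
#' @export
split_by_elevation <- function(table, threshold_m = 400) {
  ids <- covariate_unit_ids(table)
  if (!"mean_elevation" %in% names(table))
    abort("mean_elevation column required", "missing_column")
  elev <- table[["mean_elevation"]]
  if (anyNA(elev)) abort("missing values in mean_elevation", "missing_value")
  list(lowland = ids[elev < threshold_m],
       mountain = ids[elev >= threshold_m])
}

#' Read / write a covariate table as CSV
#'
#' Plain CSV with a header row, one row per unit, `unit_id` first.
#' @param path file path.
#' @return `read_covariate_table`: a data frame. `write_covariate_matrix`:
#'   `path`, invisibly.
#' @export
read_covariate_table <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path), "schema")
  tab <- read.csv(path, check.names = FALSE)
  if (!"unit_id" %in% names(tab))
    abort("covariate CSV must have a unit_id column", "schema")
  tab
}

#' @param X a `covariate_matrix` (units in rownames).
#' @rdname read_covariate_table
#' @export
write_covariate_matrix <- function(X, path) {
  df <- data.frame(unit_id = rownames(X), as.data.frame(unclass(X)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
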