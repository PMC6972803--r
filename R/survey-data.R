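## SurveyDataset: complete I x J x 2 count array plus per-unit effort.

STATUS_LEVELS <- c("dead", "alive")

#' Construct a survey dataset
#'
#' Bundles the complete species x unit x status count array with per-unit
#' surface area and kilometres travelled. Status `"dead"` corresponds to
#' roadkill detections, whose sampling effort is anchored to kilometres
#' driven; `"alive"` detections have a free per-unit effort estimated by
#' pooling all species.
#'
#' @param counts integer array I x J x 2 (species x unit x status), with
#'   `dimnames` giving species labels, unit ids and statuses
#'   `c("dead","alive")`.
#' @param surface numeric vector of unit surface areas (km^2), all > 0.
#' @param km numeric vector of kilometres travelled per unit, all >= 0.
#' @return an object of class `survey_dataset`.
#' @export
survey_dataset <- function(counts, surface, km) {
  if (length(dim(counts)) != 3L || dim(counts)[3] != 2L)
    abort("counts must be an I x J x 2 array", "bad_dimension")
  J <- dim(counts)[2]
  if (length(surface) != J || length(km) != J)
    abort("surface/km length must match unit dimension", "bad_dimension")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    abort("counts must be nonnegative integers", "schema")
  if (any(surface <= 0)) abort("surface must be positive", "schema")
  if (any(km < 0)) abort("km must be nonnegative", "schema")
  dn <- dimnames(counts)
  if (is.null(dn))
    dn <- list(paste0("sp", seq_len(dim(counts)[1])), paste0("u", seq_len(J)),
               STATUS_LEVELS)
  dn[[3]] <- STATUS_LEVELS
  dimnames(counts) <- dn
  structure(list(counts = counts,
                 species = dn[[1]], units = dn[[2]],
                 surface = setNames(as.numeric(surface), dn[[2]]),
                 km = setNames(as.numeric(km), dn[[2]])),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Survey dataset:", length(x$species), "species x", length(x$units),
      "units x 2 statuses\n")
  cat("  total detections:", sum(x$counts),
      sprintf("(%.1f%% dead)", 100 * sum(x$counts[, , "dead"]) / max(1, sum(x$counts))),
      "\n")
  cat("  km travelled:", format(sum(x$km), big.mark = ","),
      " mean surface:", round(mean(x$surface), 1), "km^2\n")
  invisible(x)
}

#' Read survey tables from CSV
#'
#' Reads a long-format sparse counts file (`species,unit,status,count`;
#' absent combinations are zero) and an effort file (`unit,km,surface`)
#' into a dense [survey_dataset()]. Unit order is taken from the effort
#' table.
#'
#' @param counts_path,effort_path CSV paths.
#' @return a `survey_dataset`.
#' @export
read_survey_tables <- function(counts_path, effort_path) {
  for (p in c(counts_path, effort_path))
    if (!file.exists(p)) abort(paste("file not found:", p), "schema")
  cts <- read.csv(counts_path, stringsAsFactors = FALSE)
  eff <- read.csv(effort_path, stringsAsFactors = FALSE)
  need_c <- c("species", "unit", "status", "count")
  if (!all(need_c %in% names(cts)))
    abort(paste("counts CSV needs columns", paste(need_c, collapse = ",")), "schema")
  if (!all(c("unit", "km", "surface") %in% names(eff)))
    abort("effort CSV needs columns unit,km,surface", "schema")
  bad <- setdiff(unique(cts$status), STATUS_LEVELS)
  if (length(bad))
    abort(paste("unknown status value(s):", paste(bad, collapse = ", ")),
          "unknown_status")
  if (anyDuplicated(cts[c("species", "unit", "status")]))
    abort("duplicate species/unit/status record in counts file",
          "duplicate_record")
  if (anyDuplicated(eff$unit)) abort("duplicate unit in effort file", "schema")
  unknown_units <- setdiff(unique(cts$unit), eff$unit)
  if (length(unknown_units))
    abort(paste("counts reference units absent from effort table:",
                paste(utils::head(unknown_units, 5), collapse = ", ")),
          "unit_mismatch")
  units <- as.character(eff$unit)
  species <- sort(unique(as.character(cts$species)))
  N <- array(0L, c(length(species), length(units), 2L),
             dimnames = list(species, units, STATUS_LEVELS))
  idx <- cbind(match(as.character(cts$species), species),
               match(as.character(cts$unit), units),
               match(cts$status, STATUS_LEVELS))
  N[idx] <- as.integer(cts$count)
  survey_dataset(N, surface = eff$surface, km = eff$km)
}

#' Write a survey dataset to CSV files
#'
#' Inverse of [read_survey_tables()]: zero cells are omitted from the
#' long-format counts file.
#' @param data a `survey_dataset`.
#' @param counts_path,effort_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_survey_tables <- function(data, counts_path, effort_path) {
  long <- expand.grid(species = data$species, unit = data$units,
                      status = STATUS_LEVELS, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$count <- as.vector(data$counts)
  long <- long[long$count > 0, , drop = FALSE]
  write.csv(long, counts_path, row.names = FALSE)
  write.csv(data.frame(unit = data$units, km = unname(data$km),
                       surface = unname(data$surface)),
            effort_path, row.names = FALSE)
  invisible(c(counts_path, effort_path))
}

## Drop units with zero km (their dead-status effort offset log V_j is
## undefined); warn rather than error so a survey with a few unvisited
## units still fits.
drop_zero_effort <- function(data) {
  keep <- data$km > 0
  if (all(keep)) return(data)
  warning(sprintf("dropping %d unit(s) with zero km travelled", sum(!keep)),
          call. = FALSE)
  survey_dataset(data$counts[, keep, , drop = FALSE],
                 data$surface[keep], data$km[keep])
}
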