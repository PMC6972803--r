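#' Published tallies of the French small-carnivore roadside survey
#'
#' Headline tallies of the 2006-2009 national small-carnivore logbook
#' survey that motivates this package: kilometres travelled by wildlife
#' officers, total mustelid detections, badger detections, the share of
#' roadkill among detections, and the number of small agricultural
#' regions (spatial units), split 531 lowland (< 400 m mean elevation) /
#' 172 mountain.
#'
#' Convenience quantities derived from them (the focal species' share of
#' detections, mean detections per unit) are recomputed by
#' [survey_arithmetic()].
#'
#' @format a named list: `km_travelled`, `detections_total`,
#'   `detections_focal`, `pct_roadkill`, `n_units`, `n_units_lowland`,
#'   `n_units_mountain`, `mean_surface_km2`.
#' @export
scsl_totals <- list(
  km_travelled = 82374899,
  detections_total = 26515,
  detections_focal = 9439,
  pct_roadkill = 74.2,
  n_units = 703,
  n_units_lowland = 531,
  n_units_mountain = 172,
  mean_surface_km2 = 766.7
)

#' Derived survey arithmetic
#'
#' Recomputes, from the printed survey totals, the focal species' share
#' of all detections (in percent) and the mean number of focal-species
#' detections per spatial unit.
#'
#' @param totals a list like [scsl_totals].
#' @return named list with `focal_share_pct` and `mean_per_unit`.
#' @export
survey_arithmetic <- function(totals = scsl_totals) {
  list(focal_share_pct = 100 * totals$detections_focal / totals$detections_total,
       mean_per_unit = totals$detections_focal / totals$n_units)
}
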