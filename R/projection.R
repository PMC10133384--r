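## Projection of a fitted favorability model onto alternative climate layer
## stacks (other periods, GCM x RCP scenarios) and comparison to a baseline.

#' Project a fitted model onto a scenario layer stack
#'
#' Computes the probability surface from the model's coefficients on the
#' scenario layers and transforms it to favorability with the training
#' n1/n0, over the same study-area mask used for the baseline.  Projection
#' is pure: the same model and layers always give identical surfaces.
#'
#' @param model a [FavorabilityModel-class]
#' @param scenario an [EnvStack-class] of scenario layers aligned to the
#'   model grid (layer codes must cover the model's variables), or a named
#'   character vector of .asc paths passed to [readEnvStack()]
#' @param mask optional [StudyAreaMask-class] (the baseline study area)
#' @param scenarioId optional label (e.g. "CCSM4_RCP85") stored on the result
#' @return a [PredictionSurface-class]; the label is available as
#'   `attr(x, "scenarioId")`
#' @export
projectScenario <- function(model, scenario, mask = NULL, scenarioId = NULL) {
  if (is.character(scenario)) scenario <- readEnvStack(scenario)
  surf <- predictSurface(model, scenario, mask = mask)
  if (!is.null(scenarioId)) attr(surf, "scenarioId") <- scenarioId
  surf
}

#' Latitudinal favorability centroid
#'
#' The favorability-weighted mean latitude sum(F * lat) / sum(F) over valid
#' cells: a single-number summary of where the favorable region sits, used
#' to quantify poleward shifts.
#'
#' @param surface a [PredictionSurface-class]
#' @param surfaceSlot `"F"` (default) or `"P"`
#' @return latitude in decimal degrees
#' @export
latitudinalCentroid <- function(surface, surfaceSlot = "F") {
  m <- slot(surface, surfaceSlot)
  ok <- surface@mask
  lat <- matrix(centerLat(surface@grid), surface@grid@nRows,
                surface@grid@nCols)
  w <- m[ok]
  if (sum(w) == 0) stop("surface sums to zero; centroid undefined")
  sum(w * lat[ok]) / sum(w)
}

#' Compare a projected surface to its baseline
#'
#' Runs the full fuzzy comparison ([compareSurfaces()]) of the projection
#' against the baseline and adds the latitudinal favorability centroid of
#' each surface and their displacement (projected minus baseline, degrees,
#' north positive) as a quantitative surrogate for the poleward shift that
#' favorability maps show visually.
#'
#' @param baseline,projected [PredictionSurface-class] objects on a common
#'   grid (baseline first: gain/loss and expansion/contraction read as
#'   changes from baseline to projection)
#' @param surface `"F"` (default) or `"P"`
#' @return a [ComparisonReport-class] with the `centroids` slot filled
#' @export
compareToBaseline <- function(baseline, projected, surface = "F") {
  rep <- compareSurfaces(baseline, projected, surface = surface)
  b <- latitudinalCentroid(baseline, surface)
  p <- latitudinalCentroid(projected, surface)
  rep@centroids <- c(baseline_lat = b, projected_lat = p, shift_deg = p - b)
  rep
}

#' Serialize a comparison report to a plain list / JSON
#'
#' @param report a [ComparisonReport-class]
#' @param path optional file; when given, the list is written as JSON
#' @return the list, invisibly when written
#' @export
reportToList <- function(report, path = NULL) {
  out <- list(indices = as.list(report@indices),
              range_change = as.list(report@change),
              proportions = as.list(report@proportions),
              centroids = as.list(report@centroids))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(out))
  }
  out
}
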