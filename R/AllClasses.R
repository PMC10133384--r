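#' Geographic grid definition
#'
#' A regular longitude/latitude grid in decimal degrees (WGS84).  Rows run
#' north to south (row 1 is the northernmost), columns west to east.  A point
#' belongs to the cell whose half-open interval \[west_i, east_i) x
#' \[south_i, north_i) contains it; the outer north and east boundaries are
#' closed so that every point inside the bounding box lands in exactly one
#' cell.
#'
#' @slot west,south,east,north bounding box, decimal degrees
#' @slot cellSize cell edge, decimal degrees
#' @slot nRows,nCols grid shape
#' @seealso [gridDefinition()]
#' @export
setClass("GridDefinition",
  representation(west = "numeric", south = "numeric", east = "numeric",
                 north = "numeric", cellSize = "numeric",
                 nRows = "integer", nCols = "integer"))

setValidity("GridDefinition", function(object) {
  msgs <- character()
  if (object@east <= object@west) msgs <- c(msgs, "east must exceed west")
  if (object@north <= object@south) msgs <- c(msgs, "north must exceed south")
  if (object@cellSize <= 0) msgs <- c(msgs, "cellSize must be positive")
  if (object@nRows < 1L || object@nCols < 1L)
    msgs <- c(msgs, "grid must have at least one row and column")
  tol <- 1e-6 * object@cellSize
  if (abs(object@west + object@nCols * object@cellSize - object@east) > tol)
    msgs <- c(msgs, "east - west is not nCols * cellSize")
  if (abs(object@north - object@nRows * object@cellSize - object@south) > tol)
    msgs <- c(msgs, "north - south is not nRows * cellSize")
  if (length(msgs)) msgs else TRUE
})

#' Stack of aligned environmental layers
#'
#' Named per-cell value matrices (e.g. ALT, BIO1...BIO19) sharing one
#' [GridDefinition-class].  Missing data are NA; after harmonization the NA
#' mask is identical across layers, so [validMask()] marks cells usable by
#' every layer.
#'
#' @slot grid a [GridDefinition-class]
#' @slot layers named list of numeric matrices, nRows x nCols each
#' @seealso [envStack()], [readEnvStack()]
#' @export
setClass("EnvStack",
  representation(grid = "GridDefinition", layers = "list"))

setValidity("EnvStack", function(object) {
  msgs <- character()
  nm <- names(object@layers)
  if (length(object@layers) == 0L) msgs <- c(msgs, "at least one layer required")
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    msgs <- c(msgs, "layers must have unique non-empty names")
  dims <- vapply(object@layers, function(m)
    is.matrix(m) && nrow(m) == object@grid@nRows && ncol(m) == object@grid@nCols,
    logical(1))
  if (!all(dims)) msgs <- c(msgs, "all layers must be matrices of the grid shape")
  if (length(msgs)) msgs else TRUE
})

#' Study-area membership mask
#'
#' Per-cell logical matrix marking the accessible study region, typically the
#' set of cells whose centers lie within a great-circle buffer of the cleaned
#' occurrence points ([buildStudyArea()]).
#'
#' @slot grid a [GridDefinition-class]
#' @slot member logical matrix, nRows x nCols, no NA
#' @export
setClass("StudyAreaMask",
  representation(grid = "GridDefinition", member = "matrix"))

setValidity("StudyAreaMask", function(object) {
  m <- object@member
  if (!is.logical(m) || nrow(m) != object@grid@nRows || ncol(m) != object@grid@nCols)
    return("member must be a logical matrix of the grid shape")
  if (anyNA(m)) return("member mask must not contain NA")
  TRUE
})

#' Presence/background model frame
#'
#' One row per study-area cell with complete predictor data: cell indices and
#' center coordinates, the 0/1 presence indicator (1 if at least one cleaned
#' occurrence record fell in the cell), and the predictor values read at the
#' cell.  Carries the presence/background counts n1 and n0 that define the
#' species' prevalence n1/(n1+n0).
#'
#' @slot grid a [GridDefinition-class]
#' @slot data data.frame with columns cellId, row, col, lon, lat, presence,
#'   then one column per predictor
#' @slot predictorNames character, predictor column names
#' @slot n1,n0 presence and background cell counts
#' @slot droppedCells number of member cells excluded for missing predictors
#' @seealso [gridRecords()]
#' @export
setClass("ModelFrame",
  representation(grid = "GridDefinition", data = "data.frame",
                 predictorNames = "character", n1 = "integer", n0 = "integer",
                 droppedCells = "integer"))

setValidity("ModelFrame", function(object) {
  msgs <- character()
  need <- c("cellId", "row", "col", "lon", "lat", "presence", object@predictorNames)
  if (!all(need %in% names(object@data)))
    msgs <- c(msgs, "data lacks required columns")
  if (object@n1 < 1L || object@n0 < 1L)
    msgs <- c(msgs, "degenerate frame: need at least one presence and one background cell")
  if (nrow(object@data) != object@n1 + object@n0)
    msgs <- c(msgs, "n1 + n0 must equal the number of rows")
  if (length(msgs)) msgs else TRUE
})

#' Fitted favorability model
#'
#' A binomial-logit presence/background model together with everything needed
#' to reproduce its favorability surface: coefficient table, the training
#' presence/background counts n1 and n0 (favorability of any surface
#' predicted from this model always uses these training counts), the
#' variable-selection trace and the train/test split seed.
#'
#' @slot intercept fitted intercept (log-odds)
#' @slot coefficients named numeric, log-odds per predictor unit
#' @slot summary data.frame: estimate, se, z, p per term
#' @slot aic model AIC
#' @slot n1,n0 training presence/background counts
#' @slot trace selection trace list (see [selectVariables()])
#' @slot splitSeed seed used for the train/test split (NA if none)
#' @seealso [fitFavorabilityModel()], [predictSurface()]
#' @export
setClass("FavorabilityModel",
  representation(intercept = "numeric", coefficients = "numeric",
                 summary = "data.frame", aic = "numeric",
                 n1 = "integer", n0 = "integer",
                 trace = "list", splitSeed = "numeric"))

setValidity("FavorabilityModel", function(object) {
  if (object@n1 < 1L || object@n0 < 1L)
    return("n1 and n0 must both be at least 1")
  if (length(object@coefficients) &&
      (is.null(names(object@coefficients)) || any(names(object@coefficients) == "")))
    return("coefficients must be named")
  TRUE
})

#' Per-cell probability and favorability surfaces
#'
#' The probability surface P (inverse-logit of the model's linear predictor)
#' and its favorability transform F on a common grid and validity mask.
#'
#' @slot grid a [GridDefinition-class]
#' @slot P,F numeric matrices of the grid shape; NA outside the mask
#' @slot mask logical matrix of valid cells
#' @seealso [predictSurface()], [favorability()]
#' @export
setClass("PredictionSurface",
  representation(grid = "GridDefinition", P = "matrix", F = "matrix",
                 mask = "matrix"))

setValidity("PredictionSurface", function(object) {
  dims <- function(m) nrow(m) == object@grid@nRows && ncol(m) == object@grid@nCols
  if (!dims(object@P) || !dims(object@F) || !dims(object@mask))
    return("P, F and mask must all have the grid shape")
  ok <- object@mask
  pv <- object@P[ok]; fv <- object@F[ok]
  if (anyNA(pv) || anyNA(fv)) return("P/F must be defined on every masked cell")
  if (any(pv < 0 | pv > 1) || any(fv < 0 | fv > 1))
    return("P and F must lie in [0, 1]")
  TRUE
})

#' Fuzzy comparison of two favorability surfaces
#'
#' All pairwise comparison statistics between two surfaces restricted to their
#' shared valid cells: overlap indices (Schoener's D, Warren's I, fuzzy
#' Jaccard, fuzzy Baroni-Urbani & Buser), fuzzy range-change accounting
#' (gain, loss, stable presence/absence, balance, and the same as fractions
#' of the first surface's favorability sum), per-cell expansion/contraction
#' overlays, and (when produced by [compareToBaseline()]) the latitudinal
#' favorability centroids and their displacement in degrees (north positive).
#'
#' @slot indices named numeric: schoener_d, warren_i, fuzzy_jaccard, fuzzy_baroni
#' @slot change named numeric: gain, loss, stable_presence, stable_absence, balance
#' @slot proportions the change entries divided by sum(F1)
#' @slot expansion,contraction per-cell maps in \[0,1\], NA outside the mask
#' @slot mask shared valid-cell mask
#' @slot grid a [GridDefinition-class]
#' @slot centroids named numeric: baseline_lat, projected_lat, shift_deg (NA
#'   unless computed by [compareToBaseline()])
#' @seealso [compareSurfaces()]
#' @export
setClass("ComparisonReport",
  representation(indices = "numeric", change = "numeric",
                 proportions = "numeric", expansion = "matrix",
                 contraction = "matrix", mask = "matrix",
                 grid = "GridDefinition", centroids = "numeric"))

## ---- accessors ------------------------------------------------------------

#' @rdname favshift-generics
#' @aliases gridDef,EnvStack-method
#' @export
setMethod("gridDef", "EnvStack", function(x) x@grid)
#' @rdname favshift-generics
#' @export
setMethod("gridDef", "StudyAreaMask", function(x) x@grid)
#' @rdname favshift-generics
#' @export
setMethod("gridDef", "ModelFrame", function(x) x@grid)
#' @rdname favshift-generics
#' @export
setMethod("gridDef", "PredictionSurface", function(x) x@grid)

#' @rdname favshift-generics
#' @export
setMethod("layerNames", "EnvStack", function(x) names(x@layers))

#' @rdname favshift-generics
#' @param layer layer code
#' @export
setMethod("layerValues", "EnvStack", function(x, layer) {
  if (!layer %in% names(x@layers))
    stop("no such layer: ", layer)
  x@layers[[layer]]
})

#' @rdname favshift-generics
#' @export
setMethod("validMask", "EnvStack", function(x)
  Reduce(`&`, lapply(x@layers, function(m) !is.na(m))))

#' @rdname favshift-generics
#' @export
setMethod("nPresence", "ModelFrame", function(x) x@n1)
#' @rdname favshift-generics
#' @export
setMethod("nBackground", "ModelFrame", function(x) x@n0)
#' @rdname favshift-generics
#' @export
setMethod("prevalence", "ModelFrame", function(x) x@n1 / (x@n1 + x@n0))
#' @rdname favshift-generics
#' @export
setMethod("nPresence", "FavorabilityModel", function(x) x@n1)
#' @rdname favshift-generics
#' @export
setMethod("nBackground", "FavorabilityModel", function(x) x@n0)
#' @rdname favshift-generics
#' @export
setMethod("prevalence", "FavorabilityModel", function(x) x@n1 / (x@n1 + x@n0))

## ---- show methods ---------------------------------------------------------

setMethod("show", "GridDefinition", function(object) {
  cat(sprintf("GridDefinition: %d rows x %d cols @ %g deg\n",
              object@nRows, object@nCols, object@cellSize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              object@west, object@east, object@south, object@north))
})

setMethod("show", "EnvStack", function(object) {
  cat(sprintf("EnvStack: %d layer(s) on %d x %d grid\n",
              length(object@layers), object@grid@nRows, object@grid@nCols))
  cat("  layers:", paste(names(object@layers), collapse = ", "), "\n")
  cat(sprintf("  valid cells: %d\n", sum(validMask(object))))
})

setMethod("show", "StudyAreaMask", function(object) {
  cat(sprintf("StudyAreaMask: %d member cells of %d\n",
              sum(object@member), length(object@member)))
})

setMethod("show", "ModelFrame", function(object) {
  cat(sprintf("ModelFrame: %d cells (n1 = %d presence, n0 = %d background)\n",
              nrow(object@data), object@n1, object@n0))
  cat(sprintf("  prevalence: %.4f\n", prevalence(object)))
  cat("  predictors:", paste(object@predictorNames, collapse = ", "), "\n")
  if (object@droppedCells > 0L)
    cat(sprintf("  (%d member cells dropped for missing predictor data)\n",
                object@droppedCells))
})

setMethod("show", "FavorabilityModel", function(object) {
  cat("FavorabilityModel (binomial logit)\n")
  cat(sprintf("  training: n1 = %d, n0 = %d (prevalence %.4f)\n",
              object@n1, object@n0, prevalence(object)))
  cat(sprintf("  AIC: %.2f\n", object@aic))
  print(object@summary, digits = 4)
})

setMethod("show", "PredictionSurface", function(object) {
  ok <- object@mask
  cat(sprintf("PredictionSurface on %d x %d grid (%d valid cells)\n",
              object@grid@nRows, object@grid@nCols, sum(ok)))
  if (any(ok))
    cat(sprintf("  P: mean %.4f   F: mean %.4f\n",
                mean(object@P[ok]), mean(object@F[ok])))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport\n  overlap:",
      paste(sprintf("%s = %.3f", names(object@indices), object@indices),
            collapse = ", "), "\n")
  cat("  range change:",
      paste(sprintf("%s = %.2f", names(object@change), object@change),
            collapse = ", "), "\n")
  if (!is.na(object@centroids["shift_deg"]))
    cat(sprintf("  latitudinal centroid shift: %+.4f deg\n",
                object@centroids["shift_deg"]))
})
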