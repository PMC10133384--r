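#' Read and write single-band rasters as ESRI ASCII grids
#'
#' The package exchanges gridded layers as ESRI ASCII grid files (.asc): a
#' six-line plain-text header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by one whitespace-separated row of values per grid
#' row, northernmost first.  Coordinates are geographic WGS84 decimal
#' degrees.
#'
#' @param path file path
#' @return `readAsciiGrid`: a list with `grid` ([GridDefinition-class]) and
#'   `values` (numeric matrix, NA where nodata); `writeAsciiGrid`: the path,
#'   invisibly.
#' @examples
#' g <- gridDefinition(west = 0, north = 2, cellSize = 1, nRows = 2, nCols = 2)
#' f <- tempfile(fileext = ".asc")
#' writeAsciiGrid(matrix(1:4, 2, 2), g, f)
#' readAsciiGrid(f)$values
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(need, keys), collapse = ", "))
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  cs <- vals[["cellsize"]]
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  grid <- gridDefinition(west = vals[["xllcorner"]],
                         north = vals[["yllcorner"]] + nr * cs,
                         cellSize = cs, nRows = nr, nCols = nc)
  body <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    stop("ASCII grid body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(grid = grid, values = m)
}

#' @rdname readAsciiGrid
#' @param values numeric matrix (nRows x nCols, row 1 = north)
#' @param grid a [GridDefinition-class]
#' @param nodata value written for NA cells
#' @export
writeAsciiGrid <- function(values, grid, path, nodata = -9999) {
  stopifnot(nrow(values) == grid@nRows, ncol(values) == grid@nCols)
  hdr <- c(paste("ncols", grid@nCols),
           paste("nrows", grid@nRows),
           paste("xllcorner", format(grid@west, digits = 12)),
           paste("yllcorner", format(grid@south, digits = 12)),
           paste("cellsize", format(grid@cellSize, digits = 12)),
           paste("NODATA_value", nodata))
  v <- values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(format(r, digits = 10, trim = TRUE),
                                         collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a directory or manifest of layers into an EnvStack
#'
#' `paths` may be a named character vector (layer code -> .asc path), an
#' unnamed vector (codes taken from file-name stems), or a directory (all
#' .asc files inside).  Layers must share the grid exactly; they are
#' harmonized to a common missing-data mask.
#'
#' @param paths character vector of .asc paths or a single directory
#' @return an [EnvStack-class]
#' @export
readEnvStack <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.asc$", full.names = TRUE)
  if (length(paths) == 0L) stop("no layers to read")
  if (is.null(names(paths)) || any(names(paths) == ""))
    names(paths) <- sub("\\.asc$", "", basename(paths))
  first <- readAsciiGrid(paths[[1L]])
  layers <- list(first$values)
  for (p in paths[-1L]) {
    r <- readAsciiGrid(p)
    same <- isTRUE(all.equal(c(r$grid@west, r$grid@north, r$grid@cellSize),
                             c(first$grid@west, first$grid@north,
                               first$grid@cellSize), tolerance = 1e-9)) &&
      r$grid@nRows == first$grid@nRows && r$grid@nCols == first$grid@nCols
    if (!same) stop("layer ", p, " is not aligned to ", paths[[1L]])
    layers <- c(layers, list(r$values))
  }
  names(layers) <- names(paths)
  envStack(first$grid, layers)
}

#' Write the layers of a stack or a surface to ASCII grids
#'
#' @param x an [EnvStack-class], [PredictionSurface-class] or
#'   [StudyAreaMask-class]
#' @param dir output directory (created if needed)
#' @param prefix optional file-name prefix
#' @return the written paths, invisibly
#' @export
writeSurfaces <- function(x, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(values, grid, name) {
    p <- file.path(dir, paste0(prefix, name, ".asc"))
    writeAsciiGrid(values, grid, p)
    p
  }
  if (is(x, "EnvStack")) {
    for (nm in layerNames(x)) paths <- c(paths, wr(x@layers[[nm]], x@grid, nm))
  } else if (is(x, "PredictionSurface")) {
    P <- x@P; P[!x@mask] <- NA; Fv <- x@F; Fv[!x@mask] <- NA
    paths <- c(wr(P, x@grid, "P"), wr(Fv, x@grid, "F"))
  } else if (is(x, "StudyAreaMask")) {
    paths <- wr(x@member + 0, x@grid, "study_area")
  } else stop("unsupported object of class ", class(x))
  invisible(paths)
}
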