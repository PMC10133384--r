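#' Create a geographic grid definition
#'
#' Either the full bounding box or (west, north) plus the shape may be given;
#' the remaining quantities are derived from `cellSize`.  When a bounding box
#' is supplied its extent must be a whole number of cells (to within 1e-6 of
#' a cell).
#'
#' @param west,north north-west corner, decimal degrees
#' @param south,east optional south-east corner
#' @param cellSize cell edge in decimal degrees (0.08333 is the usual
#'   5-arc-minute climate-layer resolution)
#' @param nRows,nCols optional grid shape (used when south/east are missing)
#' @return a [GridDefinition-class]
#' @examples
#' gridDefinition(west = -80, north = 45, cellSize = 0.5, nRows = 10, nCols = 12)
#' @export
gridDefinition <- function(west, north, cellSize, south = NULL, east = NULL,
                           nRows = NULL, nCols = NULL) {
  if (is.null(nRows)) {
    if (is.null(south)) stop("give either south or nRows")
    nRows <- as.integer(round((north - south) / cellSize))
  }
  if (is.null(nCols)) {
    if (is.null(east)) stop("give either east or nCols")
    nCols <- as.integer(round((east - west) / cellSize))
  }
  new("GridDefinition", west = west, north = north,
      south = north - nRows * cellSize, east = west + nCols * cellSize,
      cellSize = cellSize, nRows = as.integer(nRows), nCols = as.integer(nCols))
}

#' Cell-center coordinates
#'
#' Longitudes of the column centers (west to east) and latitudes of the row
#' centers (north to south, matching matrix row order).
#'
#' @param grid a [GridDefinition-class]
#' @return numeric vector
#' @export
centerLon <- function(grid) grid@west + (seq_len(grid@nCols) - 0.5) * grid@cellSize

#' @rdname centerLon
#' @export
centerLat <- function(grid) grid@north - (seq_len(grid@nRows) - 0.5) * grid@cellSize

#' All cell centers as a data frame
#'
#' @param grid a [GridDefinition-class]
#' @return data.frame with cellId, row, col, lon, lat; cellId is the
#'   row-major index (row - 1) * nCols + col with row 1 at the north edge
#' @export
cellCenters <- function(grid) {
  row <- rep(seq_len(grid@nRows), each = grid@nCols)
  col <- rep(seq_len(grid@nCols), times = grid@nRows)
  data.frame(cellId = (row - 1L) * grid@nCols + col, row = row, col = col,
             lon = centerLon(grid)[col], lat = centerLat(grid)[row])
}

#' Assign points to grid cells
#'
#' Cell membership is half-open: a point on a cell's west or south edge
#' belongs to that cell, a point on its east or north edge to the neighbour.
#' The outer east and north boundaries of the grid are closed, so points on
#' the bounding box are always assigned.  Points outside the box get NA.
#'
#' @param grid a [GridDefinition-class]
#' @param lon,lat point coordinates, decimal degrees
#' @return data.frame with row, col, cellId (NA for points off the grid)
#' @export
pointToCell <- function(grid, lon, lat) {
  stopifnot(length(lon) == length(lat))
  inside <- !is.na(lon) & !is.na(lat) &
    lon >= grid@west & lon <= grid@east &
    lat >= grid@south & lat <= grid@north
  col <- floor((lon - grid@west) / grid@cellSize) + 1
  row <- ceiling((grid@north - lat) / grid@cellSize)
  col <- pmin(col, grid@nCols)      # outer east edge closed
  row <- pmax(row, 1)               # outer north edge closed
  row[!inside] <- NA; col[!inside] <- NA
  row <- as.integer(row); col <- as.integer(col)
  data.frame(row = row, col = col,
             cellId = (row - 1L) * grid@nCols + col)
}

#' Bundle layers into an environmental stack
#'
#' @param grid a [GridDefinition-class]
#' @param layers named list of numeric matrices (nRows x nCols)
#' @param harmonize if TRUE (default), cells missing in any layer are set to
#'   NA in all layers so the missing-data mask is shared
#' @return an [EnvStack-class]
#' @export
envStack <- function(grid, layers, harmonize = TRUE) {
  layers <- lapply(layers, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  obj <- new("EnvStack", grid = grid, layers = layers)
  if (harmonize) {
    ok <- validMask(obj)
    obj@layers <- lapply(obj@layers, function(m) { m[!ok] <- NA_real_; m })
  }
  obj
}
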