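#' Read occurrence records from a CSV/TSV file
#'
#' Expects the column conventions of biodiversity-portal exports:
#' `decimalLongitude` and `decimalLatitude` are required; `year`,
#' `countryCode`, `occurrenceStatus` and `gbifID` are used when present.
#' The delimiter is auto-detected (comma or tab); the file must be UTF-8.
#' Coordinates that fail to parse become NA (and are later counted as
#' cleaning removals, not read failures).
#'
#' @param path CSV or TSV file
#' @return a data.frame with columns recordId, lon, lat, year, country,
#'   status (status normalized to "presence"/"absence"/"other"; missing
#'   status is treated as presence, the portal convention)
#' @export
readOccurrences <- function(path) {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                   comment.char = "")
  need <- c("decimalLongitude", "decimalLatitude")
  if (!all(need %in% names(df)))
    stop("occurrence file lacks required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  getcol <- function(nm) if (nm %in% names(df)) df[[nm]] else rep(NA, nrow(df))
  out <- data.frame(
    recordId = if ("gbifID" %in% names(df)) as.character(df$gbifID)
               else as.character(seq_len(nrow(df))),
    lon = suppressWarnings(as.numeric(getcol("decimalLongitude"))),
    lat = suppressWarnings(as.numeric(getcol("decimalLatitude"))),
    year = suppressWarnings(as.integer(getcol("year"))),
    country = as.character(getcol("countryCode")),
    status = normalizeStatus(getcol("occurrenceStatus")),
    stringsAsFactors = FALSE)
  out
}

normalizeStatus <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep("other", length(x))
  out[is.na(x) | x == "" | x %in% c("PRESENT", "PRESENCE", "1")] <- "presence"
  out[x %in% c("ABSENT", "ABSENCE", "0")] <- "absence"
  out
}

#' Clean occurrence records
#'
#' Applies the standard record-level filters in a fixed, logged order:
#' \enumerate{
#'   \item \code{status}: keep confirmed presences only;
#'   \item \code{invalid_coord}: drop records whose coordinates are missing,
#'     unparseable or impossible (|lon| > 180 or |lat| > 90);
#'   \item \code{zero_zero}: drop records at exactly (0, 0);
#'   \item \code{country}: if `allowedCountries` is given, keep only records
#'     whose ISO-2 country code is in the set (missing codes are dropped);
#'   \item \code{bounds}: drop records west of `lonMin` or south of `latMin`;
#'   \item \code{duplicate}: collapse records sharing (lon, lat, year) to one.
#' }
#' The removal log reports the count removed by each rule, in this order.
#' Cleaning is idempotent: re-cleaning a cleaned table removes nothing.
#'
#' @param raw data.frame as returned by [readOccurrences()] (columns recordId,
#'   lon, lat, year, country, status)
#' @param lonMin,latMin western/southern bounding limits in decimal degrees
#'   (default -Inf: no limit); the salamander study used lonMin = -94,
#'   latMin = 32
#' @param allowedCountries character vector of ISO-2 codes, or NULL to skip
#'   the country filter
#' @return list with `records` (the cleaned table) and `log` (named integer
#'   vector of removals per rule)
#' @examples
#' raw <- data.frame(recordId = as.character(1:3),
#'                   lon = c(-75, 0, -75), lat = c(42, 0, 42),
#'                   year = c(2005L, 2005L, 2005L),
#'                   country = "US", status = "presence")
#' cleanOccurrences(raw)$log
#' @export
cleanOccurrences <- function(raw, lonMin = -Inf, latMin = -Inf,
                             allowedCountries = NULL) {
  stopifnot(is.finite(lonMin) || lonMin == -Inf,
            is.finite(latMin) || latMin == -Inf)
  df <- raw
  log <- c(status = 0L, invalid_coord = 0L, zero_zero = 0L,
           country = 0L, bounds = 0L, duplicate = 0L)
  drop <- function(df, keep, rule) {
    log[[rule]] <<- log[[rule]] + sum(!keep)
    df[keep, , drop = FALSE]
  }
  df <- drop(df, df$status == "presence", "status")
  ok <- !is.na(df$lon) & !is.na(df$lat) &
    df$lon >= -180 & df$lon <= 180 & df$lat >= -90 & df$lat <= 90
  df <- drop(df, ok, "invalid_coord")
  df <- drop(df, !(df$lon == 0 & df$lat == 0), "zero_zero")
  if (!is.null(allowedCountries))
    df <- drop(df, !is.na(df$country) & df$country %in% allowedCountries,
               "country")
  df <- drop(df, df$lon >= lonMin & df$lat >= latMin, "bounds")
  key <- paste(df$lon, df$lat, df$year, sep = "\r")
  df <- drop(df, !duplicated(key), "duplicate")
  if (nrow(df) == 0L) stop("no records survive cleaning")
  rownames(df) <- NULL
  list(records = df, log = log)
}

#' Subset records to a year window
#'
#' Both bounds are inclusive; records with a missing year are dropped (they
#' cannot be assigned to a period).
#'
#' @param occ cleaned occurrence data.frame
#' @param y0,y1 first and last year of the window
#' @return the subset data.frame (a warning is issued if it is empty)
#' @export
subsetYears <- function(occ, y0, y1) {
  stopifnot(y0 <= y1)
  out <- occ[!is.na(occ$year) & occ$year >= y0 & occ$year <= y1, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no records in the window ", y0, "-", y1)
  rownames(out) <- NULL
  out
}

#' Buffer occurrence points into a study-area mask
#'
#' A cell belongs to the study area iff the haversine great-circle distance
#' (spherical Earth, radius 6371 km) from its center to the nearest
#' occurrence point is at most `radiusKm`.  With the conventional 350 km
#' buffer this delimits the region regarded as accessible to the species,
#' including unoccupied climates, which supplies the background cells.
#'
#' @param occ cleaned occurrence data.frame (columns lon, lat)
#' @param grid a [GridDefinition-class]
#' @param radiusKm buffer radius in kilometers (> 0)
#' @return a [StudyAreaMask-class]; every cell containing an occurrence point
#'   is always a member
#' @export
buildStudyArea <- function(occ, grid, radiusKm = 350) {
  if (!is.numeric(radiusKm) || radiusKm <= 0) stop("radiusKm must be positive")
  if (nrow(occ) == 0L) stop("no occurrence points to buffer")
  pts <- unique(cbind(occ$lon, occ$lat))
  lons <- centerLon(grid); lats <- centerLat(grid)
  member <- matrix(FALSE, grid@nRows, grid@nCols)
  hav <- function(a, b) geosphere::distHaversine(a, b, r = 6371000)
  # row-wise: all cell centers in a row share a latitude
  for (i in seq_len(grid@nRows)) {
    centers <- cbind(lons, rep(lats[i], grid@nCols))
    d <- geosphere::distm(centers, pts, fun = hav)
    member[i, ] <- apply(d, 1L, min) <= radiusKm * 1000
  }
  # guarantee membership of occupied cells (degenerate radii)
  cell <- pointToCell(grid, pts[, 1L], pts[, 2L])
  inb <- !is.na(cell$row)
  member[cbind(cell$row[inb], cell$col[inb])] <- TRUE
  new("StudyAreaMask", grid = grid, member = member)
}

#' Grid occurrence records into a presence/background model frame
#'
#' Thins records to one presence per grid cell (a cell is a presence iff at
#' least one cleaned record falls inside it under the half-open cell
#' convention of [pointToCell()]) and treats every other study-area cell with
#' complete environmental data as unoccupied background.  Predictor values
#' are the cell values of the environmental layers, not interpolations at
#' the record coordinates.
#'
#' @param occ cleaned occurrence data.frame
#' @param env an [EnvStack-class]
#' @param mask a [StudyAreaMask-class] on the same grid
#' @return a [ModelFrame-class] carrying n1, n0 and prevalence; member cells
#'   lacking predictor data are excluded and counted in `droppedCells`
#' @export
gridRecords <- function(occ, env, mask) {
  grid <- env@grid
  if (!identical(c(mask@grid@west, mask@grid@north, mask@grid@cellSize,
                   mask@grid@nRows, mask@grid@nCols),
                 c(grid@west, grid@north, grid@cellSize, grid@nRows, grid@nCols)))
    stop("env and mask must share the same grid")
  ok <- validMask(env)
  cells <- cellCenters(grid)
  memberVec <- as.vector(t(mask@member))   # row-major, matches cellId order
  okVec <- as.vector(t(ok))
  use <- memberVec & okVec
  dropped <- sum(memberVec & !okVec)

  pres <- rep(0L, nrow(cells))
  hit <- pointToCell(grid, occ$lon, occ$lat)
  hitIds <- unique(hit$cellId[!is.na(hit$cellId)])
  pres[hitIds] <- 1L

  df <- cells[use, , drop = FALSE]
  df$presence <- pres[use]
  for (nm in layerNames(env))
    df[[nm]] <- as.vector(t(env@layers[[nm]]))[use]
  n1 <- sum(df$presence == 1L); n0 <- sum(df$presence == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate frame: n1 = ", n1, ", n0 = ", n0)
  rownames(df) <- NULL
  new("ModelFrame", grid = grid, data = df,
      predictorNames = layerNames(env),
      n1 = as.integer(n1), n0 = as.integer(n0),
      droppedCells = as.integer(dropped))
}
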