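mkRaw <- function(lon, lat, year = 2005L, country = "US",
                  status = "presence") {
  n <- max(length(lon), length(lat), length(year), length(country),
           length(status))
  data.frame(recordId = as.character(seq_len(n)), lon = lon, lat = lat,
             year = year, country = country, status = status,
             stringsAsFactors = FALSE)
}

test_that("cleaning applies each removal rule and logs it", {
  raw <- rbind(
    mkRaw(-75, 42),                       # kept
    mkRaw(0, 0),                          # zero_zero
    mkRaw(-75, 95),                       # impossible latitude
    mkRaw(-75, NA),                       # unparseable coordinate
    mkRaw(-95, 40),                       # west of lonMin = -94
    mkRaw(-75, 31),                       # south of latMin = 32
    mkRaw(-75, 42, country = "MX"),       # country not allowed
    mkRaw(-75, 42, status = "absence"),   # not a confirmed presence
    mkRaw(-75, 42))                       # exact duplicate of row 1
  out <- cleanOccurrences(raw, lonMin = -94, latMin = 32,
                          allowedCountries = c("US", "CA"))
  expect_equal(nrow(out$records), 1L)
  expect_equal(unname(out$log),
               c(1L, 2L, 1L, 1L, 2L, 1L))
  expect_equal(names(out$log),
               c("status", "invalid_coord", "zero_zero", "country",
                 "bounds", "duplicate"))
  expect_error(cleanOccurrences(mkRaw(0, 0)), "no records survive")
})

test_that("cleaning is idempotent", {
  fx <- smallFixture(seed = 3)
  once <- fx$clean$records
  twice <- cleanOccurrences(once)
  expect_identical(twice$records[order(twice$records$recordId), ],
                   once[order(once$recordId), ])
  expect_equal(sum(twice$log), 0L)
})

test_that("year subsets are inclusive, drop missing years, and enumerate exactly", {
  years <- c(rep(NA_integer_, 10), 1940:2029)
  occ <- mkRaw(lon = seq(-80, -70, length.out = 100),
               lat = seq(35, 45, length.out = 100), year = years)
  sub <- subsetYears(occ, 1961, 2000)
  expect_equal(nrow(sub), 40L)                 # direct enumeration
  expect_true(all(sub$year >= 1961 & sub$year <= 2000))
  expect_true(1961 %in% sub$year && 2000 %in% sub$year)  # inclusive bounds
  expect_warning(subsetYears(occ, 1800, 1805), "no records")
  expect_error(subsetYears(occ, 2000, 1990))
})

test_that("study-area buffer matches a brute-force haversine oracle", {
  g <- gridDefinition(west = -80, north = 44, cellSize = 0.25,
                      nRows = 16, nCols = 16)
  pts <- mkRaw(lon = c(-79.1, -77.3), lat = c(43.2, 41.5))
  mask <- buildStudyArea(pts, g, radiusKm = 150)
  lons <- centerLon(g); lats <- centerLat(g)
  for (i in seq_len(g@nRows)) for (j in seq_len(g@nCols)) {
    d <- min(oracleHaversineKm(pts$lon, pts$lat, lons[j], lats[i]))
    expect_equal(mask@member[i, j], d <= 150,
                 info = sprintf("cell (%d,%d), distance %.1f km", i, j, d))
  }
  # a cell whose center is just beyond the radius is excluded
  dall <- outer(seq_len(g@nRows), seq_len(g@nCols), Vectorize(function(i, j)
    min(oracleHaversineKm(pts$lon, pts$lat, lons[j], lats[i]))))
  expect_true(any(dall > 150 & dall < 160))
  expect_false(any(mask@member[dall > 150]))
  expect_error(buildStudyArea(pts, g, radiusKm = 0), "positive")
})

test_that("enlarging the buffer radius never removes members, and occupied cells are always members", {
  g <- gridDefinition(west = -80, north = 44, cellSize = 0.25,
                      nRows = 12, nCols = 12)
  pts <- mkRaw(lon = c(-79.5, -78.2, -79.0), lat = c(43.5, 42.3, 42.0))
  prev <- NULL
  for (r in c(30, 80, 150, 400)) {
    mask <- buildStudyArea(pts, g, radiusKm = r)
    if (!is.null(prev)) expect_true(all(mask@member[prev]))
    prev <- mask@member
    hit <- pointToCell(g, pts$lon, pts$lat)
    expect_true(all(mask@member[cbind(hit$row, hit$col)]))
  }
  # tiny radius degenerates to the occupied cells themselves
  tiny <- buildStudyArea(pts, g, radiusKm = 1e-9)
  hit <- pointToCell(g, pts$lon, pts$lat)
  expect_equal(sum(tiny@member), length(unique(hit$cellId)))
})

test_that("gridRecords thins to one presence per cell and counts the fixture", {
  g <- gridDefinition(west = 0, north = 1, cellSize = 0.1,
                      nRows = 10, nCols = 10)
  # 60-cell circular-ish member mask, 7 occupied cells (two points share one)
  member <- matrix(FALSE, 10, 10)
  member[2:9, 2:9] <- TRUE
  member[2, 2:5] <- FALSE            # 64 - 4 = 60 member cells
  mask <- new("StudyAreaMask", grid = g, member = member)
  env <- envStack(g, list(X = matrix(rnorm(100), 10, 10)))
  cellsOcc <- data.frame(row = c(3, 3, 4, 5, 6, 7, 8), col = c(2, 5, 4, 6, 3, 8, 8))
  lon <- (cellsOcc$col - 0.5) * 0.1
  lat <- 1 - (cellsOcc$row - 0.5) * 0.1
  occ <- mkRaw(lon = c(lon, lon[1] + 0.01), lat = c(lat, lat[1] + 0.01))
  frame <- gridRecords(occ, env, mask)
  expect_equal(nPresence(frame), 7L)
  expect_equal(nBackground(frame), 53L)
  expect_equal(prevalence(frame), 7 / 60)
  # every presence row's cell contains at least one record (brute force)
  hit <- pointToCell(g, occ$lon, occ$lat)
  presRows <- frame@data[frame@data$presence == 1L, ]
  expect_setequal(presRows$cellId, unique(hit$cellId))
})

test_that("member cells with masked predictor values are excluded and logged", {
  g <- gridDefinition(west = 0, north = 1, cellSize = 0.5, nRows = 2, nCols = 2)
  X <- matrix(1:4, 2, 2); X[2, 2] <- NA
  env <- envStack(g, list(X = X))
  mask <- fullAreaMask(g)
  occ <- mkRaw(lon = 0.25, lat = 0.75)
  frame <- gridRecords(occ, env, mask)
  expect_equal(nrow(frame@data), 3L)
  expect_equal(frame@droppedCells, 1L)
  expect_error(gridRecords(mkRaw(lon = 0.6, lat = 0.4), env, mask),
               "degenerate frame")
})
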