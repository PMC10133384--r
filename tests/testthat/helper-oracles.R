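# Shared fixtures and independent oracles used across the suite.

# build a ModelFrame directly from vectors (one-column grid, n rows)
makeFrame <- function(presence, predictors) {
  n <- length(presence)
  grid <- gridDefinition(west = 0, north = n * 0.1, cellSize = 0.1,
                         nRows = n, nCols = 1L)
  df <- data.frame(cellId = seq_len(n), row = seq_len(n), col = 1L,
                   lon = 0.05, lat = centerLat(grid), presence = presence)
  for (nm in names(predictors)) df[[nm]] <- predictors[[nm]]
  new("ModelFrame", grid = grid, data = df,
      predictorNames = names(predictors),
      n1 = as.integer(sum(presence == 1L)),
      n0 = as.integer(sum(presence == 0L)), droppedCells = 0L)
}

# brute-force AUC: proportion of presence/background pairs correctly ordered,
# ties counted half
bruteAUC <- function(obs, pred) {
  p1 <- pred[obs == 1]; p0 <- pred[obs == 0]
  tot <- 0
  for (a in p1) tot <- tot + sum(a > p0) + 0.5 * sum(a == p0)
  tot / (length(p1) * length(p0))
}

# brute-force max-TSS scan over all cutpoints
bruteMaxTSS <- function(obs, pred) {
  best <- -Inf
  for (t in sort(unique(c(0, pred, 1)))) {
    hat <- pred >= t
    tss <- sum(hat & obs == 1) / sum(obs == 1) +
      sum(!hat & obs == 0) / sum(obs == 0) - 1
    if (tss > best) best <- tss
  }
  best
}

# haversine distance in km, written out from the formula (independent of
# geosphere), spherical Earth R = 6371 km
oracleHaversineKm <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  6371 * 2 * asin(pmin(1, sqrt(a)))
}

# classical binary similarity indices from 2x2 set counts
oracleBinaryJaccard <- function(x, y) {
  c_ <- sum(x == 1 & y == 1); a <- sum(x == 1 & y == 0)
  b <- sum(x == 0 & y == 1)
  c_ / (a + b + c_)
}
oracleBinaryBaroni <- function(x, y) {
  c_ <- sum(x == 1 & y == 1); a <- sum(x == 1 & y == 0)
  b <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  (sqrt(c_ * d) + c_) / (sqrt(c_ * d) + a + b + c_)
}

# a small prediction surface from a plain favorability matrix (F = P here)
surfaceFromMatrix <- function(m, grid = NULL, mask = NULL) {
  if (is.null(grid))
    grid <- gridDefinition(west = 0, north = nrow(m) * 0.1, cellSize = 0.1,
                           nRows = nrow(m), nCols = ncol(m))
  if (is.null(mask)) mask <- !is.na(m)
  new("PredictionSurface", grid = grid, P = m, F = m, mask = mask)
}

# interior bump-shaped study: favorability mass concentrated mid-grid so a
# northward field translation moves it without clipping at the domain edge
bumpStudy <- function(seed, nRows = 80L, nCols = 40L, center = 43) {
  grid <- gridDefinition(west = -75, north = 47, cellSize = 0.08333,
                         nRows = nRows, nCols = nCols)
  lat <- matrix(centerLat(grid), nRows, nCols)
  bump <- exp(-((lat - center) / 0.6)^2)
  noise <- withSeed_test(seed, matrix(rnorm(nRows * nCols, sd = 0.02),
                                      nRows, nCols))
  env <- envStack(grid, list(ENV = bump + noise))
  model <- new("FavorabilityModel", intercept = -9,
               coefficients = c(ENV = 10),
               summary = data.frame(), aic = NA_real_,
               n1 = 100L, n0 = 100L, trace = list(), splitSeed = NA_real_)
  list(grid = grid, env = env, model = model)
}

withSeed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
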