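## Virtual-species simulator: smooth environmental fields with known
## inter-layer correlation, a known logistic presence response, Bernoulli
## presence sampling, record-level corruption, and climate-shift scenarios.
## Provides ground truth for every pipeline stage without external data.

# smooth unit-variance random field: coarse white noise, bilinearly
# interpolated to the grid (low-frequency by construction), standardized
smoothField <- function(nRows, nCols) {
  kr <- max(4L, ceiling(nRows / 12)); kc <- max(4L, ceiling(nCols / 12))
  z <- matrix(rnorm(kr * kc), kr, kc)
  ry <- seq(1, nRows, length.out = kr); rx <- seq(1, nCols, length.out = kc)
  tmp <- apply(z, 2L, function(col) approx(ry, col, xout = seq_len(nRows))$y)
  out <- t(apply(tmp, 1L, function(row) approx(rx, row, xout = seq_len(nCols))$y))
  (out - mean(out)) / sd(out)
}

standardizeField <- function(m) (m - mean(m)) / sd(m)

#' Generate a stack of synthetic environmental layers
#'
#' Each layer spec is a list with elements `mean` (base value), `gradient`
#' (deterministic change per degree of latitude, emulating the dominant
#' latitudinal structure of climate layers), `noise` (amplitude of a smooth
#' low-frequency random field), and optionally `correlateWith` plus
#' `targetCor`: such a layer is built as
#' `rho * std(source) + sqrt(1 - rho^2) * std(residual noise)` scaled by
#' `noise` around `mean`, so its realized Pearson correlation with the
#' source layer equals the request exactly.  Generation is fully
#' deterministic for a fixed seed (R's default Mersenne-Twister stream,
#' double precision).
#'
#' @param grid a [GridDefinition-class]
#' @param layerSpecs named list of layer specs (names become layer codes)
#' @param seed integer seed
#' @return an [EnvStack-class]
#' @examples
#' g <- gridDefinition(west = -82, north = 47, cellSize = 0.08333,
#'                     nRows = 30, nCols = 30)
#' env <- generateEnvStack(g, list(
#'   BIO1 = list(mean = 8, gradient = -1.5, noise = 1.5),
#'   BIO11 = list(mean = -2, noise = 2, correlateWith = "BIO1",
#'                targetCor = 0.9)), seed = 1)
#' cor(as.vector(layerValues(env, "BIO1")), as.vector(layerValues(env, "BIO11")))
#' @export
generateEnvStack <- function(grid, layerSpecs, seed) {
  if (length(layerSpecs) < 1L) stop("at least one layer spec required")
  nr <- grid@nRows; nc <- grid@nCols
  latDev <- matrix(centerLat(grid) - mean(centerLat(grid)), nr, nc)
  layers <- withSeed(seed, {
    out <- list()
    for (nm in names(layerSpecs)) {
      sp <- layerSpecs[[nm]]
      mean0 <- if (is.null(sp$mean)) 0 else sp$mean
      grad <- if (is.null(sp$gradient)) 0 else sp$gradient
      amp <- if (is.null(sp$noise)) 1 else sp$noise
      if (!is.null(sp$correlateWith)) {
        rho <- sp$targetCor
        if (is.null(rho) || abs(rho) > 1)
          stop("targetCor must be given and lie in [-1, 1] for layer ", nm)
        src <- out[[sp$correlateWith]]
        if (is.null(src)) stop("layer ", nm, " correlates with unknown layer ",
                               sp$correlateWith)
        zs <- standardizeField(src)
        e <- smoothField(nr, nc)
        e <- standardizeField(e - sum(e * zs) / sum(zs * zs) * zs)
        out[[nm]] <- mean0 + amp * (rho * zs + sqrt(1 - rho^2) * e)
      } else {
        out[[nm]] <- mean0 + grad * latDev + amp * smoothField(nr, nc)
      }
    }
    out
  })
  envStack(grid, layers)
}

#' Specify a virtual species
#'
#' Bundles and validates the known environment-occurrence response and the
#' record-generation parameters used by [simulateVirtualSpecies()].
#'
#' @param intercept true intercept (log-odds)
#' @param betas named numeric, true log-odds per unit of each named layer
#'   (at least one must be nonzero)
#' @param samplingRate fraction of realized presence cells reported as
#'   occurrence records (detection), in \[0, 1\]
#' @param corruptionRates named numeric rates in \[0, 1\] for the injected
#'   record defects: duplicate, zero_zero, invalid_coord,
#'   out_of_window_year (each as a fraction of the base record count)
#' @param yearWindow integer c(first, last) year assigned to valid records
#' @param seed integer seed for the simulation
#' @return a validated list of class "VirtualSpeciesSpec"
#' @export
virtualSpeciesSpec <- function(intercept, betas, samplingRate = 0.8,
                               corruptionRates = c(duplicate = 0.05,
                                                   zero_zero = 0.05,
                                                   invalid_coord = 0.05,
                                                   out_of_window_year = 0.05),
                               yearWindow = c(2001L, 2020L), seed = 1L) {
  stopifnot(is.numeric(betas), !is.null(names(betas)))
  if (all(betas == 0)) stop("at least one beta must be nonzero")
  full <- c(duplicate = 0, zero_zero = 0, invalid_coord = 0,
            out_of_window_year = 0)
  full[names(corruptionRates)] <- corruptionRates
  if (any(full < 0 | full > 1) || samplingRate < 0 || samplingRate > 1)
    stop("rates must lie in [0, 1]")
  structure(list(intercept = intercept, betas = betas,
                 samplingRate = samplingRate, corruptionRates = full,
                 yearWindow = as.integer(yearWindow), seed = as.integer(seed)),
            class = "VirtualSpeciesSpec")
}

# uniform point inside a given cell
pointInCell <- function(grid, row, col) {
  lon <- grid@west + (col - 1 + runif(length(col))) * grid@cellSize
  lat <- grid@north - (row - 1 + runif(length(row))) * grid@cellSize
  cbind(lon, lat)
}

#' Simulate a virtual species on an environmental stack
#'
#' Computes the true probability surface P = inverse-logit(intercept +
#' sum beta * layer) on the valid cells, draws each cell's presence as
#' Bernoulli(P), and reports a `samplingRate` fraction of the presence cells
#' as occurrence records placed uniformly inside their cells with years
#' drawn from the spec's window.  Record-level corruption is then injected
#' at the stated rates: exact duplicates of base records, records at (0,0),
#' records with impossible latitudes, and otherwise-valid records with years
#' outside the window.  The true favorability surface uses the realized
#' presence/background counts, mirroring the prevalence the pipeline can
#' observe.
#'
#' @param env an [EnvStack-class]
#' @param spec a [virtualSpeciesSpec()]
#' @return list: `P` and `F` (true surfaces, NA off the valid mask),
#'   `presence` (realized 0/1 matrix), `n1`, `n0` (realized counts),
#'   `occ` (occurrence data.frame in [readOccurrences()] layout),
#'   `baseRecords` (count before corruption), `injected` (named counts of
#'   corrupted records per type)
#' @export
simulateVirtualSpecies <- function(env, spec) {
  stopifnot(inherits(spec, "VirtualSpeciesSpec"))
  missing <- setdiff(names(spec$betas), layerNames(env))
  if (length(missing))
    stop("spec betas reference unknown layer(s): ",
         paste(missing, collapse = ", "))
  grid <- env@grid
  ok <- validMask(env)
  eta <- matrix(spec$intercept, grid@nRows, grid@nCols)
  for (v in names(spec$betas))
    eta <- eta + spec$betas[[v]] * env@layers[[v]]
  P <- plogis(eta)
  P[!ok] <- NA_real_
  if (sum(P[ok]) < 10) stop("spec too sparse: expected presences below 10")

  withSeed(spec$seed, {
    pres <- matrix(0L, grid@nRows, grid@nCols)
    pres[ok] <- rbinom(sum(ok), 1L, P[ok])
    n1 <- sum(pres == 1L, na.rm = TRUE); n0 <- sum(ok) - n1
    Fv <- favorability(P, max(n1, 1L), max(n0, 1L))
    Fv[!ok] <- NA_real_

    pcells <- which(pres == 1L, arr.ind = TRUE)
    take <- runif(nrow(pcells)) < spec$samplingRate
    pcells <- pcells[take, , drop = FALSE]
    m <- nrow(pcells)
    if (m == 0L) stop("no presence cells sampled; raise samplingRate")
    xy <- pointInCell(grid, pcells[, 1L], pcells[, 2L])
    y0 <- spec$yearWindow[1L]; y1 <- spec$yearWindow[2L]
    occ <- data.frame(recordId = sprintf("base%05d", seq_len(m)),
                      lon = xy[, 1L], lat = xy[, 2L],
                      year = sample(seq(y0, y1), m, replace = TRUE),
                      country = NA_character_, status = "presence",
                      stringsAsFactors = FALSE)

    rates <- spec$corruptionRates
    nDup <- round(rates[["duplicate"]] * m)
    nZero <- round(rates[["zero_zero"]] * m)
    nInv <- round(rates[["invalid_coord"]] * m)
    nOut <- round(rates[["out_of_window_year"]] * m)
    extra <- list()
    if (nDup > 0) {
      d <- occ[sample(m, nDup, replace = FALSE), , drop = FALSE]
      d$recordId <- sprintf("dup%05d", seq_len(nDup))
      extra <- c(extra, list(d))
    }
    if (nZero > 0)
      extra <- c(extra, list(data.frame(
        recordId = sprintf("zero%05d", seq_len(nZero)), lon = 0, lat = 0,
        year = sample(seq(y0, y1), nZero, replace = TRUE),
        country = NA_character_, status = "presence",
        stringsAsFactors = FALSE)))
    if (nInv > 0)
      extra <- c(extra, list(data.frame(
        recordId = sprintf("inv%05d", seq_len(nInv)),
        lon = runif(nInv, grid@west, grid@east),
        lat = 90 + runif(nInv, 1, 5),
        year = sample(seq(y0, y1), nInv, replace = TRUE),
        country = NA_character_, status = "presence",
        stringsAsFactors = FALSE)))
    if (nOut > 0) {
      cells <- which(pres == 1L, arr.ind = TRUE)
      pick <- cells[sample(nrow(cells), nOut, replace = TRUE), , drop = FALSE]
      oxy <- pointInCell(grid, pick[, 1L], pick[, 2L])
      extra <- c(extra, list(data.frame(
        recordId = sprintf("out%05d", seq_len(nOut)),
        lon = oxy[, 1L], lat = oxy[, 2L],
        year = y0 - sample(5:40, nOut, replace = TRUE),
        country = NA_character_, status = "presence",
        stringsAsFactors = FALSE)))
    }
    occ <- do.call(rbind, c(list(occ), extra))
    occ <- occ[sample(nrow(occ)), , drop = FALSE]
    rownames(occ) <- NULL

    list(P = P, F = Fv, presence = pres, n1 = as.integer(n1),
         n0 = as.integer(n0), occ = occ, baseRecords = m,
         injected = c(duplicate = nDup, zero_zero = nZero,
                      invalid_coord = nInv, out_of_window_year = nOut))
  })
}

#' Shift a climate stack additively and/or northward
#'
#' Emulates a future-climate layer stack: per-layer additive deltas and/or a
#' rigid northward translation of every field by a whole number of cells
#' (row i takes the value of the cell `translateCells` rows to its south;
#' the newly exposed southern rows repeat the former southernmost row).
#' The grid itself is unchanged.
#'
#' @param env an [EnvStack-class]
#' @param deltas named numeric of additive shifts (layers not named are
#'   unchanged)
#' @param translateCells non-negative integer, northward translation in cells
#'   (must be smaller than the grid height)
#' @return an [EnvStack-class]
#' @export
shiftClimate <- function(env, deltas = NULL, translateCells = 0L) {
  k <- as.integer(translateCells)
  nr <- env@grid@nRows
  if (k < 0L) stop("translateCells must be non-negative (northward)")
  if (k >= nr) stop("translation must be smaller than the grid height")
  if (!is.null(deltas)) {
    missing <- setdiff(names(deltas), layerNames(env))
    if (length(missing))
      stop("deltas reference unknown layer(s): ", paste(missing, collapse = ", "))
  }
  layers <- env@layers
  if (k > 0L) {
    layers <- lapply(layers, function(m) {
      out <- m
      out[seq_len(nr - k), ] <- m[seq(k + 1L, nr), ]
      out[seq(nr - k + 1L, nr), ] <- m[rep(nr, k), ]
      out
    })
  }
  for (nm in names(deltas))
    layers[[nm]] <- layers[[nm]] + deltas[[nm]]
  envStack(env@grid, layers, harmonize = FALSE)
}

#' Study-area mask covering the whole grid
#'
#' @param grid a [GridDefinition-class]
#' @return a [StudyAreaMask-class] with every cell a member
#' @export
fullAreaMask <- function(grid)
  new("StudyAreaMask", grid = grid,
      member = matrix(TRUE, grid@nRows, grid@nCols))

defaultLayerSpecs <- function() list(
  BIO1 = list(mean = 8, gradient = -1.5, noise = 1.5),
  BIO11 = list(mean = -2, noise = 2, correlateWith = "BIO1", targetCor = 0.9),
  BIO12 = list(mean = 1000, gradient = 0, noise = 150),
  BIO4 = list(mean = 800, gradient = 20, noise = 80),
  NOI1 = list(mean = 0, noise = 1),
  NOI2 = list(mean = 0, noise = 1))

defaultSpeciesSpec <- function(seed, samplingRate = 0.8,
                               corruptionRates = c(duplicate = 0.05,
                                                   zero_zero = 0.05,
                                                   invalid_coord = 0.05,
                                                   out_of_window_year = 0.05),
                               yearWindow = c(2001L, 2020L))
  virtualSpeciesSpec(intercept = -1.6,
                     betas = c(BIO1 = -0.5, BIO12 = 0.004),
                     samplingRate = samplingRate,
                     corruptionRates = corruptionRates,
                     yearWindow = yearWindow, seed = seed)

#' Bundled synthetic study fixture
#'
#' A self-contained virtual-species study on a 60 x 60 grid at 0.08333
#' degrees: six environmental layers (a temperature-like generating layer
#' with a latitudinal gradient, a second layer correlated 0.9 with it, a
#' precipitation-like generating layer, an inert seasonality-like layer and
#' two pure-noise layers), a virtual species responding to the two
#' generating layers (intercept -1.6, betas -0.5 and 0.004, prevalence
#' about 0.2), corrupted occurrence records, cleaning, a 150 km study-area
#' buffer (scaled to the fixture's roughly 5-degree window) and the gridded
#' presence/background model frame.
#'
#' @param seed integer seed driving every random step
#' @param nRows,nCols grid shape (default 60 x 60)
#' @param samplingRate,corruptionRates,yearWindow passed to
#'   [virtualSpeciesSpec()]
#' @param bufferKm study-area buffer radius (default 150; use NA for the
#'   whole grid, skipping the buffer computation)
#' @return list with grid, env, spec, sim (see [simulateVirtualSpecies()]),
#'   clean (cleaned records + removal log), occ (era-subset records), mask,
#'   frame
#' @examples
#' fx <- smallFixture(seed = 1)
#' fx$frame
#' @export
smallFixture <- function(seed, nRows = 60L, nCols = 60L,
                         samplingRate = 0.8,
                         corruptionRates = c(duplicate = 0.05,
                                             zero_zero = 0.05,
                                             invalid_coord = 0.05,
                                             out_of_window_year = 0.05),
                         yearWindow = c(2001L, 2020L), bufferKm = 150) {
  grid <- gridDefinition(west = -82, north = 47, cellSize = 0.08333,
                         nRows = nRows, nCols = nCols)
  env <- generateEnvStack(grid, defaultLayerSpecs(), seed = seed)
  spec <- defaultSpeciesSpec(seed = seed + 1L, samplingRate = samplingRate,
                             corruptionRates = corruptionRates,
                             yearWindow = yearWindow)
  sim <- simulateVirtualSpecies(env, spec)
  clean <- cleanOccurrences(sim$occ)
  occ <- subsetYears(clean$records, yearWindow[1L], yearWindow[2L])
  mask <- if (is.na(bufferKm)) fullAreaMask(grid)
          else buildStudyArea(occ, grid, radiusKm = bufferKm)
  frame <- gridRecords(occ, env, mask)
  list(grid = grid, env = env, spec = spec, sim = sim, clean = clean,
       occ = occ, mask = mask, frame = frame)
}

#' Parameter-recovery fixture
#'
#' The fixture used for coefficient-recovery checks: a 50 x 100 grid (5000
#' cells), full detection (samplingRate 1), no record corruption and no
#' buffer restriction, so the gridded frame reproduces the realized
#' presence field exactly and the fitted coefficients estimate the known
#' betas under a correctly specified model.
#'
#' @param seed integer seed
#' @return as [smallFixture()]
#' @export
recoveryFixture <- function(seed)
  smallFixture(seed, nRows = 50L, nCols = 100L, samplingRate = 1,
               corruptionRates = c(duplicate = 0, zero_zero = 0,
                                   invalid_coord = 0, out_of_window_year = 0),
               bufferKm = NA)
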