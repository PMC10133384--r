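test_that("environment generation is deterministic and honors correlation requests", {
  g <- gridDefinition(west = -82, north = 47, cellSize = 0.08333,
                      nRows = 40, nCols = 40)
  specs <- list(A = list(mean = 5, gradient = -1, noise = 1),
                B = list(mean = 0, noise = 2, correlateWith = "A",
                         targetCor = 0.9),
                C = list(mean = 2, gradient = 0.5, noise = 0))
  e1 <- generateEnvStack(g, specs, seed = 12)
  e2 <- generateEnvStack(g, specs, seed = 12)
  expect_identical(e1@layers, e2@layers)
  e3 <- generateEnvStack(g, specs, seed = 13)
  expect_false(identical(e1@layers$A, e3@layers$A))
  # requested correlation realized (exact construction, well within 0.05)
  r <- cor(as.vector(layerValues(e1, "A")), as.vector(layerValues(e1, "B")))
  expect_equal(r, 0.9, tolerance = 1e-9)
  # zero noise amplitude: exact linear function of latitude
  C <- layerValues(e1, "C")
  lat <- centerLat(g)
  expect_equal(C[, 1], 2 + 0.5 * (lat - mean(lat)), tolerance = 1e-12)
  expect_equal(C[, 1], C[, 40])
  expect_error(generateEnvStack(g, list(A = list(), B = list(
    correlateWith = "A", targetCor = 1.2)), seed = 1), "targetCor")
})

test_that("virtual species realizes its stated presence probabilities", {
  g <- gridDefinition(west = -82, north = 47, cellSize = 0.08333,
                      nRows = 30, nCols = 30)
  env <- generateEnvStack(g, list(X = list(noise = 1)), seed = 14)
  spec <- virtualSpeciesSpec(intercept = -1, betas = c(X = 1),
                             corruptionRates = c(duplicate = 0),
                             samplingRate = 1, seed = 1)
  sims <- vapply(1:100, function(r) {
    s <- virtualSpeciesSpec(intercept = -1, betas = c(X = 1),
                            corruptionRates = c(duplicate = 0),
                            samplingRate = 1, seed = r)
    simulateVirtualSpecies(env, s)$n1
  }, integer(1))
  P <- simulateVirtualSpecies(env, spec)$P
  expP <- sum(P, na.rm = TRUE)
  sdP <- sqrt(sum(P * (1 - P), na.rm = TRUE))
  # empirical prevalence within 3 Monte-Carlo SDs of the binomial mean
  expect_lt(abs(mean(sims) - expP), 3 * sdP / sqrt(length(sims)))
  # extreme betas make the presence pattern deterministic
  det <- simulateVirtualSpecies(env, virtualSpeciesSpec(
    intercept = 0, betas = c(X = 60), samplingRate = 1,
    corruptionRates = c(duplicate = 0), seed = 5))
  expect_true(all(det$presence[det$P > 0.9999] == 1))
  expect_true(all(det$presence[det$P < 0.0001] == 0))
  expect_error(simulateVirtualSpecies(env, virtualSpeciesSpec(
    intercept = -30, betas = c(X = 0.1), seed = 1)), "too sparse")
})

test_that("cleaning recovers the injected corruption counts exactly", {
  fx <- smallFixture(seed = 15)
  inj <- fx$sim$injected
  log <- fx$clean$log
  expect_equal(log[["duplicate"]], unname(inj["duplicate"]))
  expect_equal(log[["zero_zero"]], unname(inj["zero_zero"]))
  expect_equal(log[["invalid_coord"]], unname(inj["invalid_coord"]))
  expect_equal(log[["status"]], 0L)
  # the year window recovers the out-of-window injections
  removedByYear <- nrow(fx$clean$records) - nrow(fx$occ)
  expect_equal(removedByYear, unname(inj["out_of_window_year"]))
  # and the surviving records are exactly the base ones
  expect_equal(nrow(fx$occ), fx$sim$baseRecords)
})

test_that("climate shifting applies exact deltas and edge-extended translations", {
  fx <- smallFixture(seed = 16)
  same <- shiftClimate(fx$env, deltas = c(BIO1 = 0), translateCells = 0)
  expect_equal(same@layers, fx$env@layers)
  plus2 <- shiftClimate(fx$env, deltas = c(BIO1 = 2))
  expect_equal(mean(layerValues(plus2, "BIO1")),
               mean(layerValues(fx$env, "BIO1")) + 2, tolerance = 1e-12)
  expect_identical(layerValues(plus2, "BIO12"), layerValues(fx$env, "BIO12"))
  tr <- shiftClimate(fx$env, translateCells = 3)
  A0 <- layerValues(fx$env, "BIO1"); A1 <- layerValues(tr, "BIO1")
  expect_identical(A1[1:57, ], A0[4:60, ])
  expect_identical(A1[58, ], A0[60, ])     # southern edge extension
  expect_error(shiftClimate(fx$env, translateCells = 60), "grid height")
  expect_error(shiftClimate(fx$env, deltas = c(NOPE = 1)), "NOPE")
})

test_that("the bundled fixture is deterministic and runs the pipeline stages quickly", {
  t0 <- Sys.time()
  fx1 <- smallFixture(seed = 17)
  fx2 <- smallFixture(seed = 17)
  expect_identical(fx1$sim$occ, fx2$sim$occ)
  expect_identical(fx1$frame@data, fx2$frame@data)
  expect_equal(fx1$grid@cellSize, 0.08333)
  expect_equal(length(layerNames(fx1$env)), 6L)
  # a full model cycle on the fixture stays well inside the stated minute
  sp <- splitTrainTest(fx1$frame, seed = 17)
  sel <- selectVariables(sp$train)
  m <- fitFavorabilityModel(sp$train, sel$vars, trace = sel$trace)
  ev <- evaluateModel(sp$test@data$presence, predictProbability(m, sp$test),
                      prevalence(m))
  surf <- predictSurface(m, fx1$env, fx1$mask)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 60)
  expect_gt(ev$AUC, 0.6)
})
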