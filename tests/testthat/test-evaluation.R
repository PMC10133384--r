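test_that("threshold metrics match hand arithmetic on a known confusion matrix", {
  # TP = 40, FN = 10, FP = 10, TN = 40 at threshold 0.5
  obs <- c(rep(1, 50), rep(0, 50))
  pred <- c(rep(0.9, 40), rep(0.1, 10), rep(0.9, 10), rep(0.1, 40))
  m <- thresholdMetrics(obs, pred, 0.5)
  expect_equal(m[c("TP", "FN", "FP", "TN")], list(TP = 40L, FN = 10L,
                                                  FP = 10L, TN = 40L))
  expect_equal(m$CCR, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$TSS, 0.6)
  expect_equal(m$kappa, 0.6)       # p_o = 0.8, p_e = 0.5
  # classification rule uses >= at the threshold
  expect_equal(thresholdMetrics(c(1, 0), c(0.5, 0.4), 0.5)$TP, 1L)
})

test_that("degenerate classifications behave as documented", {
  obs <- c(1, 1, 0, 0)
  perfect <- thresholdMetrics(obs, c(0.9, 0.8, 0.2, 0.1), 0.5)
  expect_equal(perfect$CCR, 1); expect_equal(perfect$TSS, 1)
  expect_equal(perfect$kappa, 1)
  # constant prediction: kappa = 0, precision undefined below threshold
  const <- thresholdMetrics(obs, rep(0.3, 4), 0.2)
  expect_equal(const$kappa, 0)
  expect_warning(none <- thresholdMetrics(obs, rep(0.3, 4), 0.9),
                 "precision undefined")
  expect_true(is.na(none$precision))
})

test_that("max-TSS threshold scan agrees with the brute-force oracle", {
  obs <- c(1, 1, 0, 0); pred <- c(0.9, 0.4, 0.6, 0.1)
  mx <- maxTSSThreshold(obs, pred)
  expect_equal(mx$TSS, 0.5)
  expect_equal(mx$threshold, 0.4)          # smallest attaining the max
  expect_equal(mx$TSS, bruteMaxTSS(obs, pred))
  # perfectly separated and constant predictions
  expect_equal(maxTSSThreshold(obs, c(0.9, 0.8, 0.2, 0.1))$TSS, 1)
  expect_equal(maxTSSThreshold(obs, rep(0.5, 4))$TSS, 0)
  # random cases against the oracle
  for (r in 1:25) {
    v <- withSeed_test(r, list(o = rbinom(40, 1, 0.4),
                               p = round(runif(40), 2)))
    if (length(unique(v$o)) < 2) next
    expect_equal(maxTSSThreshold(v$o, v$p)$TSS, bruteMaxTSS(v$o, v$p))
  }
})

test_that("rank-based AUC equals brute-force pair counting, with midrank ties", {
  obs <- c(1, 1, 0, 0); pred <- c(0.9, 0.4, 0.6, 0.1)
  expect_equal(rocAUC(obs, pred), 0.75)
  expect_equal(rocAUC(obs, c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(rocAUC(obs, rep(0.4, 4)), 0.5)     # all tied
  for (r in 1:50) {
    v <- withSeed_test(1000 + r, list(o = rbinom(60, 1, 0.3),
                                      p = round(runif(60), 1)))
    if (length(unique(v$o)) < 2) next
    expect_equal(rocAUC(v$o, v$p), bruteAUC(v$o, v$p))
  }
  expect_error(rocAUC(rep(1, 5), runif(5)), "both classes")
})

test_that("Miller calibration is exact on in-sample fits and detects overconfidence", {
  fx <- withSeed_test(31, {
    x <- rnorm(2000)
    obs <- rbinom(2000, 1, plogis(-1 + 1.5 * x))
    list(x = x, obs = obs)
  })
  fit <- glm(fx$obs ~ fx$x, family = binomial())
  cal <- millerCalibration(fx$obs, fitted(fit))
  expect_equal(cal$slope, 1, tolerance = 1e-6)
  expect_equal(cal$intercept, 0, tolerance = 1e-6)

  # doubling the logit halves the calibration slope
  big <- withSeed_test(32, {
    x <- rnorm(20000)
    eta <- -0.5 + x
    list(obs = rbinom(20000, 1, plogis(eta)), pred = plogis(2 * eta))
  })
  cal2 <- millerCalibration(big$obs, big$pred)
  expect_equal(cal2$slope, 0.5, tolerance = 0.05)

  expect_error(millerCalibration(c(1, 0, 1), rep(0.5, 3)),
               "calibration undefined")
})

test_that("observation-prediction correlation reproduces the t statistic", {
  # r = 0.5, n = 27 -> t = 0.5 * sqrt(25 / 0.75), df = 25
  v <- withSeed_test(33, {
    repeat {
      o <- rbinom(27, 1, 0.5)
      if (sd(o) > 0) break
    }
    o
  })
  p <- 0.2 + 0.6 * v + withSeed_test(34, rnorm(27, sd = 0.05))
  res <- obsPredCorrelation(v, p)
  expect_equal(res$t, res$r * sqrt((27 - 2) / (1 - res$r^2)))
  expect_equal(res$df, 25L)
  expect_equal(res$p, 2 * pt(-abs(res$t), 25))
  # frozen arithmetic at r exactly 0.5
  expect_equal(0.5 * sqrt(25 / 0.75), 2.8867513, tolerance = 1e-6)
  # agreement with the standard test
  ct <- cor.test(v, p)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_error(obsPredCorrelation(rep(1, 10), runif(10)), "zero variance")
})

test_that("independent predictions yield about the nominal false-positive rate", {
  hits <- vapply(1:400, function(r) {
    v <- withSeed_test(2000 + r, list(o = rbinom(50, 1, 0.5), p = runif(50)))
    if (sd(v$o) == 0) return(NA)
    obsPredCorrelation(v$o, v$p)$p < 0.05
  }, logical(1))
  rate <- mean(hits, na.rm = TRUE)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
})

test_that("the full evaluation report is internally consistent", {
  fx <- smallFixture(seed = 8)
  sp <- splitTrainTest(fx$frame, seed = 8)
  m <- fitFavorabilityModel(sp$train, c("BIO1", "BIO12"))
  ev <- evaluateModel(sp$test@data$presence, predictProbability(m, sp$test),
                      prevalenceThreshold = prevalence(m))
  for (blk in list(ev$at_prevalence, ev$at_max_tss)) {
    expect_equal(blk$TSS, blk$sensitivity + blk$specificity - 1)
    expect_equal(blk$TP + blk$FP + blk$FN + blk$TN, nrow(sp$test@data))
  }
  expect_gte(ev$at_max_tss$TSS, ev$at_prevalence$TSS - 1e-12)
  expect_gt(ev$AUC, 0.5)
  expect_lt(ev$correlation$p, 0.05)
})
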