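# frames for selection tests are generated, seeded logistic draws
simFrame <- function(seed, n, betas, intercept = -1) {
  withSeed_test(seed, {
    X <- as.data.frame(matrix(rnorm(n * length(betas)), n,
                              dimnames = list(NULL, names(betas))))
    eta <- intercept + as.matrix(X) %*% betas
    presence <- rbinom(n, 1, plogis(eta))
    if (all(presence == presence[1])) presence[1:2] <- c(0L, 1L)
    makeFrame(presence, X)
  })
}

test_that("correlation pruning drops the less informative member of each offending pair", {
  fr <- simFrame(1, 800, c(A = 1.5, Bn = 0, C = 0.3))
  # Bn highly correlated with A but pure noise w.r.t. the response
  fr@data$Bn <- 0.95 * scale(fr@data$A)[, 1] +
    sqrt(1 - 0.95^2) * withSeed_test(2, rnorm(800))
  pr <- correlationPrune(fr, rThreshold = 0.8)
  expect_true("A" %in% pr$vars)
  expect_false("Bn" %in% pr$vars)
  expect_equal(pr$trace$dropped, "Bn")
  # oracle: the dropped one has the higher single-predictor AIC
  aicA <- AIC(glm(presence ~ A, binomial, fr@data))
  aicB <- AIC(glm(presence ~ Bn, binomial, fr@data))
  expect_true(aicB > aicA)
  expect_gt(abs(pr$trace$r), 0.8)
})

test_that("identical columns collapse to one; a pair exactly at the threshold is kept", {
  fr <- simFrame(3, 300, c(A = 1, C = 0.5))
  fr@data$A2 <- fr@data$A
  fr@predictorNames <- c("A", "C", "A2")
  pr <- correlationPrune(fr)
  expect_length(pr$vars, 2L)
  expect_true(xor("A" %in% pr$vars, "A2" %in% pr$vars))

  # construct a pair with |r| = 0.8 exactly: threshold is strict
  z1 <- scale(withSeed_test(4, rnorm(400)))[, 1]
  z2 <- scale(withSeed_test(5, rnorm(400)))[, 1]
  z2 <- scale(z2 - sum(z1 * z2) / sum(z1^2) * z1)[, 1]
  x2 <- 0.8 * z1 + sqrt(1 - 0.64) * z2
  fr2 <- simFrame(6, 400, c(P = 0, Q = 0))
  fr2@data$P <- z1; fr2@data$Q <- x2
  expect_equal(cor(fr2@data$P, fr2@data$Q), 0.8, tolerance = 1e-12)
  pr2 <- correlationPrune(fr2, rThreshold = 0.8)
  expect_setequal(pr2$vars, c("P", "Q"))

  fr3 <- simFrame(7, 100, c(A = 1))
  fr3@data$K <- 5
  fr3@predictorNames <- c("A", "K")
  expect_warning(pr3 <- correlationPrune(fr3), "constant")
  expect_equal(pr3$vars, "A")
})

test_that("FDR screening reproduces Benjamini-Hochberg arithmetic", {
  # frozen case: p = (0.01, 0.02, 0.2) at q = 0.05 -> BH adjusted
  # (0.03, 0.03, 0.2) -> first two retained
  expect_equal(p.adjust(c(0.01, 0.02, 0.2), "BH"), c(0.03, 0.03, 0.2))
  fr <- simFrame(8, 2000, c(G = 2, N1 = 0, N2 = 0))
  fd <- fdrFilter(fr, c("G", "N1", "N2"))
  expect_true("G" %in% fd$vars)              # generating covariate: p ~ 0
  expect_lt(fd$trace$p[fd$trace$variable == "G"], 1e-10)
  expect_equal(p.adjust(fd$trace$p, "BH"), fd$trace$adjusted_p)
})

test_that("pure-noise predictors survive the FDR screen at about the nominal rate", {
  retained <- vapply(1:200, function(r) {
    fr <- simFrame(400 + r, 120, setNames(rep(0, 8), paste0("N", 1:8)))
    length(suppressWarnings(fdrFilter(fr, paste0("N", 1:8)))$vars) / 8
  }, numeric(1))
  # under the global null BH controls FWER at q, so the mean retained
  # fraction stays below q within Monte-Carlo error
  se <- sd(retained) / sqrt(length(retained))
  expect_lt(mean(retained), 0.05 + 3 * se)
})

test_that("stepwise AIC keeps a strong covariate and refuses redundant additions", {
  kept <- vapply(1:50, function(r) {
    fr <- simFrame(100 + r, 2000, c(G = 1.5, N1 = 0, N2 = 0, N3 = 0))
    "G" %in% stepwiseAIC(fr, c("G", "N1", "N2", "N3"))$vars
  }, logical(1))
  expect_gte(mean(kept), 0.95)

  # a near-duplicate of a selected variable carries no deviance gain, so
  # the +2 AIC penalty removes it and it is never re-added
  fr <- simFrame(9, 1000, c(G = 1.5))
  fr@data$Gdup <- fr@data$G + withSeed_test(90, rnorm(1000, sd = 0.01))
  fr@predictorNames <- c("G", "Gdup")
  st <- stepwiseAIC(fr, c("G"))
  expect_equal(st$vars, "G")
  full <- stepwiseAIC(fr, c("G", "Gdup"))
  expect_length(full$vars, 1L)
  # AIC never worsens along the path
  expect_true(all(diff(st$path$AIC_after) <= 0))
})

test_that("the FDR + stepwise cascade returns an intercept-only model on null data", {
  empty <- vapply(1:50, function(r) {
    fr <- simFrame(200 + r, 400, c(N1 = 0, N2 = 0, N3 = 0))
    fd <- suppressWarnings(fdrFilter(fr, c("N1", "N2", "N3")))
    if (length(fd$vars) == 0L) return(TRUE)
    length(stepwiseAIC(fr, fd$vars)$vars) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("trimming removes non-significant variables, largest p first", {
  fr <- simFrame(10, 2000, c(G = 1.5))
  tr <- trimNonsignificant(fr, "G")
  expect_equal(tr$vars, "G")                 # all significant: unchanged
  expect_equal(nrow(tr$trimmed), 0L)

  removed <- vapply(1:50, function(r) {
    fr <- simFrame(300 + r, 2000, c(G = 1.5, N = 0))
    !("N" %in% trimNonsignificant(fr, c("G", "N"))$vars)
  }, logical(1))
  expect_gte(mean(removed), 0.9)
})

test_that("of two collinear weak covariates exactly one is trimmed and the survivor is significant", {
  fr <- withSeed_test(11, {
    n <- 600
    x1 <- rnorm(n)
    x2 <- x1 + rnorm(n, sd = 0.15)          # heavy collinearity
    presence <- rbinom(n, 1, plogis(-0.5 + 0.5 * x1))
    makeFrame(presence, data.frame(X1 = x1, X2 = x2))
  })
  # jointly neither is significant, individually the survivor is
  sm <- coef(summary(glm(presence ~ X1 + X2, binomial, fr@data)))
  expect_true(any(sm[-1, "Pr(>|z|)"] >= 0.05))
  tr <- trimNonsignificant(fr, c("X1", "X2"))
  expect_length(tr$vars, 1L)
  expect_equal(nrow(tr$trimmed), 1L)
  refit <- coef(summary(glm(stats::reformulate(tr$vars, "presence"),
                            binomial, fr@data)))
  expect_lt(refit[tr$vars, "Pr(>|z|)"], 0.05)
})

test_that("the cascade is deterministic and never raises the post-screen AIC", {
  fx <- smallFixture(seed = 4)
  sel1 <- selectVariables(fx$frame)
  sel2 <- selectVariables(fx$frame)
  expect_identical(sel1$vars, sel2$vars)
  expect_identical(sel1$trace$stepwise_path, sel2$trace$stepwise_path)
  # stepwise never accepts a worsening move: final AIC <= starting AIC
  path <- sel1$trace$stepwise_path
  expect_true(all(path$AIC_after <= path$AIC_after[1] + 1e-9))
  # no retained pair exceeds the pruning threshold
  vars <- sel1$vars
  if (length(vars) >= 2) {
    cm <- abs(cor(fx$frame@data[vars]))
    diag(cm) <- 0
    expect_lte(max(cm), 0.8)
  }
})
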