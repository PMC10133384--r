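#' The favorability transform
#'
#' Converts presence probability P into favorability
#' \deqn{F = \frac{P/(1-P)}{n_1/n_0 + P/(1-P)},}
#' where n1 and n0 are the numbers of presence and background cells in the
#' training data.  F rescales P so that its value no longer depends on the
#' species' prevalence: F = 0.5 exactly when P equals the prevalence
#' n1/(n1+n0), F > 0.5 where conditions are better than expected by chance,
#' and F < 0.5 where they are worse.  F is strictly increasing in P, with
#' F(0) = 0 and F(1) = 1 (by limit).  When n1 = n0 the transform is the
#' identity.  Because F is commensurable across models, favorability surfaces
#' from different periods or scenarios can be combined with fuzzy logic
#' without thresholding.
#'
#' P is clipped to \[1e-12, 1 - 1e-12\] before forming odds, so exact 0 and 1
#' map to 0 and 1 without overflow.
#'
#' @param P probability value(s) in \[0, 1\]; vector or matrix (NA passes
#'   through)
#' @param n1,n0 training presence and background counts (both >= 1)
#' @return favorability on the same shape as `P`
#' @examples
#' favorability(0.5, n1 = 20, n0 = 80)   # 0.8
#' favorability(20 / 100, n1 = 20, n0 = 80)  # 0.5: P at prevalence
#' @export
favorability <- function(P, n1, n0) {
  stopifnot(n1 >= 1, n0 >= 1)
  if (any(P < 0 | P > 1, na.rm = TRUE)) stop("P must lie in [0, 1]")
  Pc <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  odds <- Pc / (1 - Pc)
  Fv <- odds / (n1 / n0 + odds)
  Fv[P == 0] <- 0
  Fv[P == 1] <- 1
  Fv
}

#' Stratified train/test split of a model frame
#'
#' Splits the frame into training and test parts, sampling `testFrac` of the
#' presence cells and of the background cells separately so both sides keep
#' the frame's prevalence (stratification by class).  Reproducible for a
#' fixed seed; the caller's RNG stream is left untouched.
#'
#' @param frame a [ModelFrame-class]
#' @param testFrac fraction held out for testing, in (0, 1) (default 0.2)
#' @param seed integer seed for the split
#' @return list with `train` and `test` [ModelFrame-class] objects
#' @export
splitTrainTest <- function(frame, testFrac = 0.2, seed) {
  stopifnot(testFrac > 0, testFrac < 1)
  df <- frame@data
  idx1 <- which(df$presence == 1L); idx0 <- which(df$presence == 0L)
  nt1 <- round(length(idx1) * testFrac)
  nt0 <- round(length(idx0) * testFrac)
  if (nt1 < 1L || nt0 < 1L || nt1 >= length(idx1) || nt0 >= length(idx0))
    stop("a stratum is too small to split at testFrac = ", testFrac)
  pick <- withSeed(seed, {
    c(sample(idx1, nt1), sample(idx0, nt0))
  })
  mk <- function(rows) {
    d <- df[rows, , drop = FALSE]; rownames(d) <- NULL
    new("ModelFrame", grid = frame@grid, data = d,
        predictorNames = frame@predictorNames,
        n1 = as.integer(sum(d$presence == 1L)),
        n0 = as.integer(sum(d$presence == 0L)),
        droppedCells = 0L)
  }
  list(train = mk(setdiff(seq_len(nrow(df)), pick)), test = mk(sort(pick)))
}

#' Fit the binomial-logit favorability model
#'
#' Maximum-likelihood logistic regression of the presence indicator on the
#' selected predictors (IRLS, deviance tolerance 1e-8, at most 100
#' iterations).  The fitted object stores the coefficient table and the
#' training n1/n0 that every later favorability transform must reuse.
#' Non-convergence, or the effectively infinite estimates produced by
#' complete separation, raise an error naming the offending variables.
#'
#' @param frame training [ModelFrame-class]
#' @param vars predictor names to fit (e.g. from [selectVariables()]); may be
#'   empty for an intercept-only model
#' @param trace optional selection trace to store with the model
#' @param splitSeed optional seed of the train/test split, stored for
#'   reproducibility
#' @return a [FavorabilityModel-class]
#' @examples
#' fx <- smallFixture(seed = 1)
#' m <- fitFavorabilityModel(fx$frame, c("BIO1", "BIO12"))
#' m@coefficients
#' @export
fitFavorabilityModel <- function(frame, vars, trace = list(), splitSeed = NA) {
  data <- frameData(frame)
  fit <- suppressWarnings(fitGlmOn(data, vars))
  sm <- coef(summary(fit))
  if (!is.matrix(sm)) sm <- matrix(sm, nrow = 1,
                                   dimnames = list("(Intercept)", names(sm)))
  bad <- rownames(sm)[abs(sm[, "Estimate"]) > 50 | sm[, "Std. Error"] > 100]
  bad <- setdiff(bad, "(Intercept)")
  if (!fit$converged)
    stop("model did not converge for variables: ", paste(vars, collapse = ", "))
  if (length(bad))
    stop("apparent complete separation involving: ", paste(bad, collapse = ", "))
  est <- sm[, "Estimate"]
  names(est) <- rownames(sm)
  summary <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], z = sm[, "z value"],
                        p = sm[, "Pr(>|z|)"], row.names = NULL,
                        stringsAsFactors = FALSE)
  coefs <- est[names(est) != "(Intercept)"]
  new("FavorabilityModel",
      intercept = unname(est[["(Intercept)"]]),
      coefficients = coefs,
      summary = summary, aic = AIC(fit),
      n1 = as.integer(sum(data$presence == 1L)),
      n0 = as.integer(sum(data$presence == 0L)),
      trace = trace, splitSeed = as.numeric(splitSeed))
}

linearPredictorFrame <- function(model, data) {
  eta <- rep(model@intercept, nrow(data))
  for (v in names(model@coefficients)) {
    if (!v %in% names(data))
      stop("new data lacks model variable(s): ",
           paste(setdiff(names(model@coefficients), names(data)),
                 collapse = ", "))
    eta <- eta + model@coefficients[[v]] * data[[v]]
  }
  eta
}

#' @rdname predictProbability
#' @param mask optional [StudyAreaMask-class]; prediction is restricted to
#'   member cells with valid data in every model layer
#' @export
setMethod("predictProbability", signature("FavorabilityModel", "EnvStack"),
  function(model, newdata, mask = NULL) {
    need <- names(model@coefficients)
    missing <- setdiff(need, layerNames(newdata))
    if (length(missing))
      stop("environment stack lacks model layer(s): ",
           paste(missing, collapse = ", "))
    grid <- newdata@grid
    eta <- matrix(model@intercept, grid@nRows, grid@nCols)
    for (v in need) eta <- eta + model@coefficients[[v]] * newdata@layers[[v]]
    ok <- if (length(need)) Reduce(`&`, lapply(newdata@layers[need],
                                               function(m) !is.na(m)))
          else matrix(TRUE, grid@nRows, grid@nCols)
    if (!is.null(mask)) ok <- ok & mask@member
    P <- plogis(eta)
    P[!ok] <- NA_real_
    attr(P, "mask") <- ok
    P
  })

#' @rdname predictProbability
#' @export
setMethod("predictProbability", signature("FavorabilityModel", "data.frame"),
  function(model, newdata) plogis(linearPredictorFrame(model, newdata)))

#' @rdname predictProbability
#' @export
setMethod("predictProbability", signature("FavorabilityModel", "ModelFrame"),
  function(model, newdata) plogis(linearPredictorFrame(model, newdata@data)))

#' Predict probability and favorability surfaces
#'
#' Applies the model to an environmental stack, producing the probability
#' surface P and its favorability transform F.  F always uses the model's
#' training n1/n0, so surfaces for other periods or scenarios stay on the
#' training model's favorability scale.
#'
#' @param model a [FavorabilityModel-class]
#' @param env an [EnvStack-class] providing every model layer
#' @param mask optional [StudyAreaMask-class]
#' @return a [PredictionSurface-class]
#' @export
predictSurface <- function(model, env, mask = NULL) {
  P <- predictProbability(model, env, mask = mask)
  ok <- attr(P, "mask")
  attr(P, "mask") <- NULL
  Fv <- favorability(P, model@n1, model@n0)
  new("PredictionSurface", grid = env@grid, P = P, F = Fv, mask = ok)
}
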