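## Discrimination and calibration metrics for presence/background models.

#' Confusion-matrix metrics at a probability threshold
#'
#' Classifies a cell as predicted-present iff its predicted probability is
#' greater than or equal to `threshold`, then reports the usual
#' threshold-dependent metrics: correct classification rate, sensitivity,
#' specificity, precision, Cohen's kappa (chance agreement from the marginal
#' products) and the true skill statistic TSS = sensitivity + specificity -
#' 1.  The species' prevalence is the classical threshold choice for
#' favorability work; [maxTSSThreshold()] provides the max-TSS alternative.
#'
#' @param obs 0/1 observation vector (both classes present)
#' @param pred predicted probabilities, same length
#' @param threshold classification cutoff
#' @return named list: threshold, TP, FP, FN, TN, CCR, sensitivity,
#'   specificity, precision, kappa, TSS (precision is NA with a warning when
#'   nothing is predicted present)
#' @examples
#' thresholdMetrics(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.1), 0.5)$TSS
#' @export
thresholdMetrics <- function(obs, pred, threshold) {
  checkObsPred(obs, pred)
  hat <- as.integer(pred >= threshold)
  TP <- sum(hat == 1L & obs == 1L); FP <- sum(hat == 1L & obs == 0L)
  FN <- sum(hat == 0L & obs == 1L); TN <- sum(hat == 0L & obs == 0L)
  n <- TP + FP + FN + TN
  sens <- TP / (TP + FN); spec <- TN / (TN + FP)
  prec <- if (TP + FP == 0L) {
    warning("no cells predicted present: precision undefined")
    NA_real_
  } else TP / (TP + FP)
  po <- (TP + TN) / n
  pe <- ((TP + FN) * (TP + FP) + (TN + FP) * (TN + FN)) / n^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  list(threshold = threshold, TP = TP, FP = FP, FN = FN, TN = TN,
       CCR = po, sensitivity = sens, specificity = spec, precision = prec,
       kappa = kappa, TSS = sens + spec - 1)
}

#' Threshold maximizing the true skill statistic
#'
#' Scans every distinct predicted value (plus 0 and 1) as a candidate cutoff
#' and returns the smallest threshold attaining the maximal TSS.
#'
#' @inheritParams thresholdMetrics
#' @return list with `threshold` and `TSS`
#' @export
maxTSSThreshold <- function(obs, pred) {
  checkObsPred(obs, pred)
  cand <- sort(unique(c(0, pred, 1)))
  # cumulative counts: for threshold t, predicted present iff pred >= t
  tss <- vapply(cand, function(t) {
    hat <- pred >= t
    sum(hat & obs == 1L) / sum(obs == 1L) +
      sum(!hat & obs == 0L) / sum(obs == 0L) - 1
  }, numeric(1))
  best <- max(tss)
  list(threshold = cand[which(tss == best)[1L]], TSS = best)
}

#' Rank-based area under the ROC curve
#'
#' AUC as the Mann–Whitney probability that a randomly chosen presence cell
#' scores above a randomly chosen background cell, with ties counted half
#' (midranks); identical to trapezoidal integration of the ROC curve.
#'
#' @inheritParams thresholdMetrics
#' @return AUC in \[0, 1\]
#' @export
rocAUC <- function(obs, pred) {
  checkObsPred(obs, pred)
  r <- rank(pred)   # midranks for ties
  n1 <- sum(obs == 1L); n0 <- sum(obs == 0L)
  (sum(r[obs == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Miller calibration test
#'
#' Logistic regression of the 0/1 observations on the logit of the predicted
#' probabilities.  A perfectly calibrated model has slope 1 and intercept 0;
#' slopes below 1 indicate overconfident (too extreme) predictions, above 1
#' underconfident ones.  Predictions are clipped away from 0/1 before taking
#' logits; a constant logit leaves the regression undefined.
#'
#' @inheritParams thresholdMetrics
#' @return list with `intercept` and `slope`
#' @export
millerCalibration <- function(obs, pred) {
  checkObsPred(obs, pred)
  l <- qlogis(pmin(pmax(pred, 1e-12), 1 - 1e-12))
  if (sd(l) == 0) stop("calibration undefined: constant logit of predictions")
  fit <- suppressWarnings(glm(obs ~ l, family = binomial()))
  list(intercept = unname(coef(fit)[1L]), slope = unname(coef(fit)[2L]))
}

#' Observation–prediction correlation test
#'
#' Pearson (point-biserial) correlation between the 0/1 observations and the
#' predictions, with the usual t statistic t = r sqrt((n-2)/(1-r^2)) on n-2
#' degrees of freedom and a two-sided p-value.  Cells are treated as
#' independent.
#'
#' @inheritParams thresholdMetrics
#' @return list with `r`, `t`, `df`, `p`
#' @export
obsPredCorrelation <- function(obs, pred) {
  n <- length(obs)
  if (n < 3L) stop("need at least 3 observations")
  if (sd(obs) == 0 || sd(pred) == 0)
    stop("zero variance in observations or predictions")
  r <- cor(obs, pred)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, df = n - 2L, p = 2 * pt(-abs(t), df = n - 2L))
}

checkObsPred <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("obs and pred lengths differ")
  if (anyNA(obs) || anyNA(pred)) stop("obs/pred must not contain NA")
  if (!all(obs %in% c(0L, 1L))) stop("obs must be 0/1")
  if (length(unique(obs)) < 2L) stop("obs must contain both classes")
  invisible(TRUE)
}

#' Full evaluation report for a fitted model
#'
#' Computes, on the supplied observations and predicted probabilities
#' (typically the held-out test split), the threshold metrics at the model's
#' training prevalence and at the max-TSS threshold, the rank-based AUC, the
#' Miller calibration intercept and slope, and the observation–prediction
#' correlation test.
#'
#' @param obs 0/1 observation vector
#' @param pred predicted probabilities
#' @param prevalenceThreshold probability cutoff used for the
#'   prevalence-based metrics (the training prevalence n1/(n1+n0))
#' @return list with elements `at_prevalence`, `at_max_tss` (each a
#'   [thresholdMetrics()] list), `AUC`, `miller`, `correlation`
#' @examples
#' fx <- smallFixture(seed = 1)
#' sp <- splitTrainTest(fx$frame, seed = 1)
#' m <- fitFavorabilityModel(sp$train, c("BIO1", "BIO12"))
#' ev <- evaluateModel(sp$test@data$presence,
#'                     predictProbability(m, sp$test),
#'                     prevalenceThreshold = prevalence(m))
#' ev$AUC
#' @export
evaluateModel <- function(obs, pred, prevalenceThreshold) {
  mx <- maxTSSThreshold(obs, pred)
  list(at_prevalence = thresholdMetrics(obs, pred, prevalenceThreshold),
       at_max_tss = thresholdMetrics(obs, pred, mx$threshold),
       AUC = rocAUC(obs, pred),
       miller = millerCalibration(obs, pred),
       correlation = obsPredCorrelation(obs, pred))
}
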