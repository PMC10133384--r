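## Variable-selection cascade for presence/background binomial GLMs:
## correlation pruning -> FDR screening -> forward-backward stepwise AIC ->
## significance trimming.  All stages are deterministic given the frame and
## thresholds.

frameData <- function(frame) {
  if (is(frame, "ModelFrame")) frame@data else as.data.frame(frame)
}

fitGlmOn <- function(data, vars, epsilon = 1e-8, maxit = 100) {
  fml <- if (length(vars) == 0L) presence ~ 1
         else stats::reformulate(vars, response = "presence")
  glm(fml, family = binomial(), data = data,
      control = glm.control(epsilon = epsilon, maxit = maxit))
}

singleVarAIC <- function(data, var) AIC(fitGlmOn(data, var))

#' Prune highly correlated predictor pairs
#'
#' While any predictor pair has |Pearson r| strictly above `rThreshold`, the
#' worst-offending pair is resolved by dropping the member whose
#' single-predictor binomial GLM has the higher AIC — i.e. the one with the
#' less informative individual relationship with the species' presence.
#' Constant predictors (undefined correlation) are dropped first with a
#' warning.  A pair at exactly the threshold is kept.
#'
#' @param frame a [ModelFrame-class]
#' @param vars candidate predictor names (default: all frame predictors)
#' @param rThreshold correlation threshold (default 0.8)
#' @return list with `vars` (retained, original order) and `trace`
#'   (data.frame kept / dropped / r, one row per resolved pair)
#' @export
correlationPrune <- function(frame, vars = NULL, rThreshold = 0.8) {
  data <- frameData(frame)
  if (is.null(vars)) vars <- frame@predictorNames
  if (length(vars) < 1L) stop("no candidate predictors")
  const <- vars[vapply(vars, function(v) sd(data[[v]]) == 0, logical(1))]
  if (length(const)) {
    warning("dropping constant predictor(s): ", paste(const, collapse = ", "))
    vars <- setdiff(vars, const)
  }
  trace <- data.frame(kept = character(), dropped = character(), r = numeric(),
                      stringsAsFactors = FALSE)
  aicCache <- new.env(parent = emptyenv())
  getAIC <- function(v) {
    if (is.null(aicCache[[v]])) aicCache[[v]] <- singleVarAIC(data, v)
    aicCache[[v]]
  }
  while (length(vars) >= 2L) {
    cm <- abs(cor(data[vars]))
    diag(cm) <- 0
    # strictly above the threshold offends; 1e-10 guards fp noise so a pair
    # at exactly the threshold is kept
    if (max(cm) <= rThreshold + 1e-10) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    a <- vars[idx[1L]]; b <- vars[idx[2L]]
    # drop the higher single-model AIC; ties: drop the alphabetically later
    dropv <- if (getAIC(a) > getAIC(b)) a
             else if (getAIC(b) > getAIC(a)) b
             else sort(c(a, b))[2L]
    keepv <- setdiff(c(a, b), dropv)
    trace <- rbind(trace, data.frame(kept = keepv, dropped = dropv,
                                     r = cor(data[[a]], data[[b]]),
                                     stringsAsFactors = FALSE))
    vars <- setdiff(vars, dropv)
  }
  list(vars = vars, trace = trace)
}

#' Screen predictors by false discovery rate
#'
#' Each candidate gets a p-value from the likelihood-ratio test of its
#' single-predictor binomial GLM against the intercept-only model; the
#' p-values are Benjamini–Hochberg adjusted across the candidate set and
#' predictors with adjusted p below `q` are retained.
#'
#' @inheritParams correlationPrune
#' @param q FDR level (default 0.05)
#' @return list with `vars` (retained) and `trace` (data.frame variable / p /
#'   adjusted_p / retained)
#' @export
fdrFilter <- function(frame, vars, q = 0.05) {
  data <- frameData(frame)
  if (length(vars) < 1L) stop("no candidate predictors")
  null <- fitGlmOn(data, character())
  p <- vapply(vars, function(v) {
    fit <- fitGlmOn(data, v)
    pchisq(null$deviance - fit$deviance, df = 1L, lower.tail = FALSE)
  }, numeric(1))
  adj <- p.adjust(p, method = "BH")
  keep <- adj < q
  if (!any(keep))
    warning("FDR screen removed every candidate predictor")
  list(vars = vars[keep],
       trace = data.frame(variable = vars, p = unname(p),
                          adjusted_p = unname(adj), retained = unname(keep),
                          stringsAsFactors = FALSE))
}

#' Forward-backward stepwise selection by AIC
#'
#' Starts from the full model on `vars` and repeatedly evaluates every
#' single-variable removal and every addition from the pool of currently
#' excluded candidates, applying the move with the lowest AIC whenever it
#' improves on the current model.  Ties are broken toward the smaller model,
#' then alphabetically.  Candidate fits that fail to converge are skipped
#' with a warning.
#'
#' @inheritParams correlationPrune
#' @param vars candidate predictors (typically the FDR-retained set)
#' @return list with `vars` (selected, possibly empty = intercept-only) and
#'   `path` (data.frame action / variable / AIC_after, first row the start)
#' @export
stepwiseAIC <- function(frame, vars) {
  data <- frameData(frame)
  pool <- sort(unique(vars))
  current <- pool
  tryAIC <- function(vs) {
    fit <- tryCatch(suppressWarnings(fitGlmOn(data, vs)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("skipping non-convergent candidate model: ",
              if (length(vs)) paste(vs, collapse = "+") else "(intercept only)")
      return(NA_real_)
    }
    AIC(fit)
  }
  curAIC <- tryAIC(current)
  if (is.na(curAIC)) stop("starting model did not converge")
  path <- data.frame(action = "start", variable = "",
                     AIC_after = curAIC, stringsAsFactors = FALSE)
  repeat {
    cand <- data.frame(action = character(), variable = character(),
                       size = integer(), aic = numeric(),
                       stringsAsFactors = FALSE)
    for (v in current)
      cand <- rbind(cand, data.frame(action = "remove", variable = v,
                                     size = length(current) - 1L,
                                     aic = tryAIC(setdiff(current, v))))
    for (v in setdiff(pool, current))
      cand <- rbind(cand, data.frame(action = "add", variable = v,
                                     size = length(current) + 1L,
                                     aic = tryAIC(c(current, v))))
    cand <- cand[!is.na(cand$aic), , drop = FALSE]
    if (nrow(cand) == 0L) break
    # order: lowest AIC, then smaller model, then alphabetical
    cand <- cand[order(cand$aic, cand$size, cand$variable), , drop = FALSE]
    best <- cand[1L, ]
    if (best$aic >= curAIC) break
    current <- if (best$action == "remove") setdiff(current, best$variable)
               else c(current, best$variable)
    curAIC <- best$aic
    path <- rbind(path, data.frame(action = best$action,
                                   variable = best$variable,
                                   AIC_after = curAIC,
                                   stringsAsFactors = FALSE))
  }
  list(vars = intersect(vars, current), path = path)
}

#' Remove non-significant variables after stepwise selection
#'
#' Iteratively refits the model on the current set and removes the variable
#' with the largest Wald p-value while that p-value is at or above `alpha`,
#' stopping when every remaining variable is significant (or the set is
#' empty, with a warning: no favorability model can be built then).
#'
#' @inheritParams correlationPrune
#' @param vars variables selected by [stepwiseAIC()]
#' @param alpha significance level (default 0.05)
#' @return list with `vars` (final set) and `trimmed` (data.frame variable /
#'   p_at_removal)
#' @export
trimNonsignificant <- function(frame, vars, alpha = 0.05) {
  data <- frameData(frame)
  trimmed <- data.frame(variable = character(), p_at_removal = numeric(),
                        stringsAsFactors = FALSE)
  while (length(vars) > 0L) {
    fit <- fitGlmOn(data, vars)
    sm <- coef(summary(fit))
    p <- sm[rownames(sm) != "(Intercept)", "Pr(>|z|)"]
    names(p) <- rownames(sm)[rownames(sm) != "(Intercept)"]
    if (all(p < alpha)) break
    worst <- names(p)[order(-p, names(p))][1L]
    trimmed <- rbind(trimmed, data.frame(variable = worst,
                                         p_at_removal = unname(p[worst]),
                                         stringsAsFactors = FALSE))
    vars <- setdiff(vars, worst)
  }
  if (length(vars) == 0L)
    warning("trimming removed every variable; no significant predictors remain")
  list(vars = vars, trimmed = trimmed)
}

#' Run the full variable-selection cascade
#'
#' Applies, in fixed order: [correlationPrune()] (|r| > `corThreshold`
#' resolved by single-model AIC), [fdrFilter()] (Benjamini–Hochberg at
#' `fdrQ`), [stepwiseAIC()] (forward-backward from the full post-screen
#' model), and [trimNonsignificant()] (largest Wald p first at `trimAlpha`).
#'
#' @inheritParams correlationPrune
#' @param corThreshold,fdrQ,trimAlpha stage thresholds (defaults 0.8, 0.05,
#'   0.05)
#' @return list with `vars` (final ordered set) and `trace`, a list holding
#'   each stage's records (dropped_by_correlation, dropped_by_fdr,
#'   stepwise_path, trimmed, final_vars)
#' @examples
#' fx <- smallFixture(seed = 1)
#' sel <- selectVariables(fx$frame)
#' sel$vars
#' @export
selectVariables <- function(frame, vars = NULL, corThreshold = 0.8,
                            fdrQ = 0.05, trimAlpha = 0.05) {
  if (is.null(vars)) vars <- frame@predictorNames
  pr <- correlationPrune(frame, vars, rThreshold = corThreshold)
  fd <- fdrFilter(frame, pr$vars, q = fdrQ)
  if (length(fd$vars) == 0L)
    return(list(vars = character(),
                trace = list(dropped_by_correlation = pr$trace,
                             dropped_by_fdr = fd$trace,
                             stepwise_path = NULL, trimmed = NULL,
                             final_vars = character())))
  st <- stepwiseAIC(frame, fd$vars)
  tr <- trimNonsignificant(frame, st$vars, alpha = trimAlpha)
  list(vars = tr$vars,
       trace = list(dropped_by_correlation = pr$trace,
                    dropped_by_fdr = fd$trace,
                    stepwise_path = st$path,
                    trimmed = tr$trimmed,
                    final_vars = tr$vars))
}
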