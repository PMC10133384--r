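## Fuzzy-set comparison of favorability surfaces.  Favorability values are
## degrees of membership in the fuzzy set of favorable sites, so surfaces are
## compared directly -- intersection = min, union = max -- with no
## presence/absence thresholding.

# extract paired vectors over the shared valid mask from two surfaces
pairedValues <- function(s1, s2, surface = c("F", "P")) {
  surface <- match.arg(surface)
  if (is(s1, "PredictionSurface") && is(s2, "PredictionSurface")) {
    g1 <- s1@grid; g2 <- s2@grid
    if (g1@nRows != g2@nRows || g1@nCols != g2@nCols)
      stop("surfaces must share the same grid")
    ok <- s1@mask & s2@mask
    m1 <- slot(s1, surface); m2 <- slot(s2, surface)
    list(x = m1[ok], y = m2[ok], mask = ok, grid = g1)
  } else {
    x <- as.numeric(s1); y <- as.numeric(s2)
    if (length(x) != length(y)) stop("surfaces must have equal length")
    ok <- !is.na(x) & !is.na(y)
    list(x = x[ok], y = y[ok], mask = NULL, grid = NULL)
  }
}

#' Schoener's D overlap between two surfaces
#'
#' Each surface is normalized to sum to one over the shared valid cells
#' (p_i = F_i / sum F); D = 1 - 0.5 * sum |p1 - p2|, ranging from 0
#' (disjoint) to 1 (identical normalized surfaces).
#'
#' @param s1,s2 [PredictionSurface-class] objects on a common grid, or
#'   plain numeric vectors/matrices of membership values
#' @param surface which surface to compare when given prediction surfaces:
#'   favorability `"F"` (default) or probability `"P"`
#' @return overlap in \[0, 1\]
#' @examples
#' schoenerD(c(0.2, 0.8), c(0.6, 0.4))  # 0.6
#' @export
schoenerD <- function(s1, s2, surface = "F") {
  v <- pairedValues(s1, s2, surface)
  sx <- sum(v$x); sy <- sum(v$y)
  if (sx == 0 || sy == 0) stop("a surface sums to zero on the shared cells")
  1 - 0.5 * sum(abs(v$x / sx - v$y / sy))
}

#' Warren's I overlap between two surfaces
#'
#' One minus half the squared Hellinger distance between the normalized
#' surfaces: I = 1 - 0.5 * sum (sqrt(p1) - sqrt(p2))^2.
#'
#' @inheritParams schoenerD
#' @return overlap in \[0, 1\]
#' @export
warrenI <- function(s1, s2, surface = "F") {
  v <- pairedValues(s1, s2, surface)
  sx <- sum(v$x); sy <- sum(v$y)
  if (sx == 0 || sy == 0) stop("a surface sums to zero on the shared cells")
  1 - 0.5 * sum((sqrt(v$x / sx) - sqrt(v$y / sy))^2)
}

#' Fuzzy Jaccard and Baroni-Urbani & Buser similarity
#'
#' Classical binary similarity indices generalized to graded memberships
#' with fuzzy cardinalities: A = sum F1, B = sum F2, shared presence
#' C = sum min(F1, F2), shared absence D0 = sum min(1 - F1, 1 - F2).  Then
#' Jaccard = C / (A + B - C) and Baroni = (sqrt(C D0) + C) /
#' (sqrt(C D0) + A + B - C).  On crisp 0/1 surfaces both reduce exactly to
#' their classical forms.
#'
#' @inheritParams schoenerD
#' @param index `"jaccard"` or `"baroni"`
#' @return similarity in \[0, 1\]
#' @examples
#' fuzzySimilarity(c(0.2, 0.8), c(0.6, 0.4), "jaccard")  # 0.6 / 1.4
#' @export
fuzzySimilarity <- function(s1, s2, index = c("jaccard", "baroni"),
                            surface = "F") {
  index <- match.arg(index)
  v <- pairedValues(s1, s2, surface)
  A <- sum(v$x); B <- sum(v$y)
  C <- sum(pmin(v$x, v$y))
  if (A + B - C == 0) stop("both surfaces are empty")
  if (index == "jaccard") return(C / (A + B - C))
  D0 <- sum(pmin(1 - v$x, 1 - v$y))
  (sqrt(C * D0) + C) / (sqrt(C * D0) + A + B - C)
}

#' Fuzzy range change between two favorability surfaces
#'
#' Fuzzy-cardinality accounting of how favorability moved from surface 1 to
#' surface 2 over the shared valid cells: gain = sum max(F2 - F1, 0),
#' loss = sum max(F1 - F2, 0), stable presence = sum min(F1, F2), stable
#' absence = sum min(1 - F1, 1 - F2), balance = gain - loss
#' (= sum (F2 - F1)).  Each quantity is also returned as a proportion of
#' sum F1, so balance reads as relative change from the first period.
#'
#' @inheritParams schoenerD
#' @return list with `change` (named vector: gain, loss, stable_presence,
#'   stable_absence, balance) and `proportions` (the same divided by sum F1)
#' @export
fuzzyRangeChange <- function(s1, s2, surface = "F") {
  v <- pairedValues(s1, s2, surface)
  gain <- sum(pmax(v$y - v$x, 0)); loss <- sum(pmax(v$x - v$y, 0))
  change <- c(gain = gain, loss = loss,
              stable_presence = sum(pmin(v$x, v$y)),
              stable_absence = sum(pmin(1 - v$x, 1 - v$y)),
              balance = gain - loss)
  sx <- sum(v$x)
  list(change = change,
       proportions = if (sx > 0) change / sx else change * NA_real_)
}

#' Per-cell fuzzy expansion and contraction overlays
#'
#' expansion_i = max(F2_i - F1_i, 0) and contraction_i = max(F1_i - F2_i, 0);
#' cells invalid in either surface are NA.
#'
#' @inheritParams schoenerD
#' @param op `"expansion"` or `"contraction"`
#' @return per-cell map, same shape as the inputs
#' @export
fuzzyOverlay <- function(s1, s2, op = c("expansion", "contraction"),
                         surface = "F") {
  op <- match.arg(op)
  if (is(s1, "PredictionSurface")) {
    v <- pairedValues(s1, s2, surface)
    out <- matrix(NA_real_, v$grid@nRows, v$grid@nCols)
    d <- if (op == "expansion") v$y - v$x else v$x - v$y
    out[v$mask] <- pmax(d, 0)
    out
  } else {
    d <- if (op == "expansion") s2 - s1 else s1 - s2
    pmax(d, 0)
  }
}

#' Full fuzzy comparison of two surfaces
#'
#' Bundles the overlap indices ([schoenerD()], [warrenI()],
#' [fuzzySimilarity()]), the fuzzy range-change accounting
#' ([fuzzyRangeChange()]) and the expansion/contraction overlays
#' ([fuzzyOverlay()]) into one [ComparisonReport-class].  The comparison is
#' restricted to the intersection of the two valid masks.
#'
#' @inheritParams schoenerD
#' @return a [ComparisonReport-class]
#' @export
compareSurfaces <- function(s1, s2, surface = "F") {
  v <- pairedValues(s1, s2, surface)
  if (is.null(v$grid))
    stop("compareSurfaces needs PredictionSurface inputs; ",
         "use the individual index functions for plain vectors")
  rc <- fuzzyRangeChange(s1, s2, surface)
  new("ComparisonReport",
      indices = c(schoener_d = schoenerD(s1, s2, surface),
                  warren_i = warrenI(s1, s2, surface),
                  fuzzy_jaccard = fuzzySimilarity(s1, s2, "jaccard", surface),
                  fuzzy_baroni = fuzzySimilarity(s1, s2, "baroni", surface)),
      change = rc$change, proportions = rc$proportions,
      expansion = fuzzyOverlay(s1, s2, "expansion", surface),
      contraction = fuzzyOverlay(s1, s2, "contraction", surface),
      mask = v$mask, grid = v$grid,
      centroids = c(baseline_lat = NA_real_, projected_lat = NA_real_,
                    shift_deg = NA_real_))
}
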