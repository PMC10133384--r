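---
title: "Favorability models and fuzzy range change: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Favorability models and fuzzy range change: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(favshift)
```

This vignette is the package's own account of the statistics it implements:
the model and its assumptions, the tunable parameters and why their defaults
are what they are, what the virtual-species simulator does and does not
emulate, the numerical conventions, and the places where the design was
genuinely open and a choice had to be made.

## The model

`favshift` fits presence/background species distribution models. Occurrence
records are thinned to one presence per grid cell; every other cell of the
accessible study area with complete environmental data is treated as
unoccupied background (0). The response of the species to the environment is
a binomial GLM with logit link,

$$\operatorname{logit} P_i = \beta_0 + \sum_j \beta_j x_{ij},$$

fitted by IRLS. Its output $P_i$ is a presence *probability*, which mixes
two things: the species' response to the predictors, and the overall
prevalence $n_1/(n_1+n_0)$ of presences among modelled cells. The
favorability transform removes the second ingredient:

$$F \;=\; \frac{P/(1-P)}{\,n_1/n_0 + P/(1-P)\,},$$

with $n_1$ and $n_0$ the presence and background counts of the *training*
data. Properties that the package asserts as tests:

* $F = 0.5$ exactly when $P$ equals the training prevalence, for any
  $(n_1, n_0)$;
* $F \equiv P$ when $n_1 = n_0$;
* $F$ is strictly increasing in $P$, with $F(0)=0$ and $F(1)=1$ in the
  limit;
* for a rare species ($n_1 < n_0$) $F > P$ everywhere in $(0,1)$, and the
  reverse for a common one.

Because $F$ is on a common, prevalence-free scale, the per-cell values can
be read as degrees of membership in the fuzzy set of favorable sites.
Surfaces from different eras or climate scenarios are then compared with
fuzzy-set operations (intersection = min, union = max):

* **Overlap indices** on surfaces normalized to sum 1:
  Schoener's $D = 1 - \tfrac12\sum_i |p_{1i} - p_{2i}|$ and Warren's
  $I = 1 - \tfrac12\sum_i (\sqrt{p_{1i}} - \sqrt{p_{2i}})^2$.
* **Fuzzy similarity** with fuzzy cardinalities $A=\sum F_1$, $B=\sum F_2$,
  $C=\sum\min(F_1,F_2)$, $D_\varnothing=\sum\min(1-F_1,1-F_2)$:
  Jaccard $= C/(A+B-C)$ and Baroni–Urbani & Buser
  $= (\sqrt{C D_\varnothing}+C)/(\sqrt{C D_\varnothing}+A+B-C)$. On crisp
  0/1 surfaces both reduce exactly to their classical binary forms (a
  property test).
* **Fuzzy range change**: gain $\sum\max(F_2-F_1,0)$, loss
  $\sum\max(F_1-F_2,0)$, stable presence $\sum\min(F_1,F_2)$, stable absence
  $\sum\min(1-F_1,1-F_2)$, balance = gain − loss $= \sum(F_2-F_1)$; each is
  also reported as a fraction of $\sum F_1$ so that "balance" reads as
  relative change from the earlier surface. Per-cell expansion and
  contraction maps are the positive and negative parts of $F_2-F_1$.

No step ever binarizes a surface; the only thresholds in the package are the
evaluation cutoffs, which are diagnostics, not part of the comparison
machinery.

## The selection cascade

Predictors are selected on the training split only, in a fixed order:

1. **Correlation pruning** (`cor_threshold`, default 0.8): while any pair of
   candidates has $|r|$ strictly above the threshold, the worst pair is
   resolved by dropping the member whose single-predictor GLM has the higher
   AIC. "Strictly above" matters: a pair at exactly 0.8 is kept (a 1e-10
   guard absorbs floating-point noise). "More informative individually"
   could also have been operationalized as lower p-value or higher deviance
   explained; single-model AIC was chosen because it is scale-free and
   consistent with the criterion the stepwise stage uses.
2. **FDR screening** (`fdr_q`, default 0.05): single-predictor
   likelihood-ratio p-values, Benjamini–Hochberg adjusted across the
   candidate set; retain adjusted $p < q$. The level is a convention; 0.05
   is the field's default.
3. **Stepwise AIC**, forward–backward, starting from the full post-screen
   model. All single additions and removals are scored; the best move is
   applied only if it lowers the AIC; ties break toward the smaller model,
   then alphabetically, making the procedure fully deterministic.
4. **Trimming** (`trim_alpha`, default 0.05): refit, drop the largest Wald
   p at or above the level, repeat. Dropping largest-first with refits
   handles collinear pairs correctly: of two jointly non-significant but
   individually significant covariates, exactly one is removed.

A property worth stating because it is easy to get wrong: stepwise AIC
*alone* is not a null filter. Under a pure-null response, a noise variable
survives stepwise whenever its deviance gain exceeds 2, which happens with
probability about 0.16 — so with several noise candidates an intercept-only
outcome is not even likely. It is the FDR screen in front of it that
controls the null retention rate (under the global null, BH keeps anything
with probability about $q$), and the package's null-data test therefore
exercises the FDR → stepwise cascade, not stepwise in isolation. The
end-to-end study-level test shows the full cascade retains each pure-noise
layer in well under 10% of simulated studies, while the generating layers
are kept in over 95%.

## Evaluation

All evaluation happens on the held-out test split (20%, stratified by class
so both sides keep the training prevalence; the split seed is stored on the
model). The prevalence of the *training* data is the default classification
threshold — for favorability-based work it is the natural cutoff, since it
corresponds to $F = 0.5$ — with the max-TSS threshold as the standard
alternative. Predicted-presence uses $\ge$ at the threshold, so a prediction
exactly at the cutoff counts as a presence call.

* TSS = sensitivity + specificity − 1 (asserted as an identity on every
  report the suite produces).
* Cohen's kappa uses chance agreement from the marginal products; it is 0
  for any constant prediction vector and 1 only for a diagonal confusion
  matrix.
* AUC is the rank-based (Mann–Whitney) form with midranks for ties, equal to
  trapezoidal ROC integration; the suite checks it against brute-force pair
  counting on hundreds of random fixtures.
* Miller calibration regresses the 0/1 outcomes on the logit of the
  predicted probabilities; slope 1 / intercept 0 is a fixed point for a
  model's own in-sample fitted values (the calibration score equations are
  a subset of the original model's), which the suite verifies to 1e-6.
* The observation–prediction correlation test is the usual point-biserial
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. It treats cells as independent;
  no spatial autocorrelation correction is attempted.

## The virtual species

The simulator exists so every stage has ground truth without external
downloads. Its pieces:

* **Fields**: each layer is mean + latitudinal gradient + a smooth
  low-frequency random field (coarse white noise, bilinearly interpolated,
  standardized), deterministic under R's default Mersenne-Twister stream in
  double precision. A layer can request a target correlation with an earlier
  layer; the request is honored *exactly* (empirically, not just in
  expectation) by projecting the residual noise orthogonal to the source and
  mixing with weights $\rho$ and $\sqrt{1-\rho^2}$.
* **Species**: $P_i$ from a known logistic response; presences are
  independent Bernoulli draws per cell. True favorability uses the realized
  presence/background counts — the quantity the pipeline could at best see.
* **Records**: a `samplingRate` fraction of presence cells yields one record
  each, placed uniformly inside the cell. Corruption is injected at stated
  rates: exact duplicates, (0,0) records, impossible latitudes, and
  otherwise-valid records with out-of-window years. The cleaning log
  recovers each injected count exactly (a test), with out-of-window years
  recovered by the era subset rather than the cleaner, mirroring where each
  rule lives in the pipeline.
* **Scenarios**: additive per-layer deltas and/or rigid northward
  translation by whole cells, southern edge rows extended.

The default study conditions: a 60 × 60 grid at 0.08333°, six layers — a
temperature-like generating layer (gradient −1.5 °C per degree latitude,
smooth noise sd 1.5, true coefficient −0.5), a decoy correlated 0.9 with it,
a precipitation-like generating layer (sd 150 mm, true coefficient +0.004),
an inert seasonality-like layer, and two pure-noise layers — intercept −1.6
(prevalence ≈ 0.2), 80% detection, 5% corruption of each kind, and a 150 km
buffer (scaled to the fixture's ≈5° window; the conventional 350 km default
would cover the whole toy grid). Parameter-recovery checks use a 50 × 100
grid (5000 cells), full detection and no corruption, so the model is
correctly specified and Wald coverage is interpretable.

What the simulator deliberately does **not** emulate: spatially
autocorrelated detection error, observer effort gradients, non-climatic
drivers, and dispersal limitation. Passing tests therefore demonstrate that
the machinery is correct under a known response with independent cell-level
noise — not that any real species satisfies those assumptions.

## Numerical conventions and degenerate inputs

* Cell membership is half-open, $[w, e) \times [s, n)$, with the grid's
  outer north and east boundaries closed, so a point on any edge lands in
  exactly one cell and gridding is deterministic.
* The study-area buffer is a haversine great-circle distance (spherical
  Earth, $R = 6371$ km) from cell centers to the nearest record — a
  geographic-distance reading of "buffer", rather than a polygon union in a
  projected CRS. Cells containing records are members regardless of radius,
  so the radius → 0 limit degenerates to the occupied cells.
* $P$ is clipped to $[10^{-12}, 1-10^{-12}]$ before odds are formed, so the
  favorability transform and Miller logits never overflow; exact 0 and 1
  map to $F = 0$ and 1.
* Duplicates are records identical in (lon, lat, year) after coordinate
  parsing; near-duplicates across datasets are not merged.
* Records lacking a year are excluded from era subsets (they cannot be
  assigned to a period); era bounds are inclusive.
* GLMs use deviance tolerance 1e-8 with at most 100 IRLS iterations;
  non-convergence and effectively-infinite estimates (complete separation)
  are errors naming the variables, not silent results. Constant predictors
  are dropped before correlation pruning, where their correlation is
  undefined.
* Comparisons of two surfaces are restricted to the intersection of their
  valid masks; a surface summing to zero there is an error, not a NaN.

## Open design points and how they were resolved

* **Selection data**: the cascade runs on the 80% training split, keeping
  the held-out 20% untouched for evaluation. Running selection on all data
  would leak information into the test metrics.
* **Overlap surface**: Schoener's D and Warren's I are computed on
  favorability by default — it is the comparable scale — with `surface="P"`
  available where probability-scale overlap is wanted.
* **Range-change normalizer**: proportions divide by $\sum F_1$, so gain,
  loss and balance read as fractions of the earlier period's favorability.
* **Centroid statistic**: the latitudinal favorability centroid
  $\sum F \cdot \mathrm{lat} / \sum F$ and its displacement quantify
  "northward shift" numerically. One caveat found while validating it: for
  a response monotone in latitude the favorable mass sits against the
  domain edge, a translation clips it, and the centroid displacement is
  genuinely smaller than the imposed shift. The translation-recovery test
  therefore uses an interior (bump-shaped) favorability field, where
  displacement matches the imposed $k \cdot$ cellSize within one cell and
  the interior rows translate bit-exactly.
* **Missing occurrence status** is treated as presence (the biodiversity
  portal convention for the field's exports); explicit absences and
  anything unrecognized are removed and logged.

## Problem sizes in the shipped suite

The test suite simulates everything it needs at run time: the bundled study
is 3600 cells, selection-cascade property tests use 400–2000 observations
with 50–200 replicates, AUC and fuzzy reductions use 200–500 random
fixtures, calibration slope recovery uses 20 000 draws, and the study-level
recovery test runs 100 replicates of the 5000-cell fixture. The whole suite
runs in under two minutes on one CPU; the sizes were chosen so Monte-Carlo
error is comfortably inside the asserted bounds.

## Limitations

* Presence/background designs estimate relative, not absolute, occurrence
  rates; favorability corrects for prevalence in the *sample* of cells, not
  for detection bias in the records.
* Cells are treated as independent in fitting and in the correlation test;
  spatial autocorrelation will make reported p-values optimistic on real
  data.
* Only linear terms enter the GLM — no interactions, polynomials, penalized
  fits or spatial random effects; GAM/Maxent-style engines are an explicit
  extension point, not implemented.
* Scenario projection assumes the fitted response transfers to the new
  climate (no dispersal, no biotic interactions, no layer bias correction).
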