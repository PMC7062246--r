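---
title: "Methods: models, thresholds, and the synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds, and the synthetic test world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the
presence-background modeling procedure it implements, the assumptions and
tunable parameters that matter, what the synthetic-data generator does and
does not emulate, the numerical conventions, and the design choices made
where the design was genuinely open. It states no empirical result that the
test suite does not itself compute.

## The modeling problem

Presence-background species distribution modeling contrasts locations where
a species was recorded against a sample of "background" locations that
characterize the available environment. The fitted scorer maps a vector of
environmental predictors to a relative habitat suitability in [0, 1]. For
invasive plants the products that matter to practitioners are binary
suitable/unsuitable maps under explicit thresholds, agreement counts across
models (an equal-weight ensemble), flags for environmental extrapolation
(MESS), and per-management-unit area summaries.

All coordinates are assumed planar in an equal-area projection; cell sizes,
buffers and distances are in map units (meters under the intended use). The
analysis grid convention is half-open cell ownership: a point on a shared
edge belongs to the cell to its right, or below it in map space.

## Occurrence cleaning

Records are retained when the type is observation or specimen, the event
year is ≥ 1980, and the coordinate uncertainty is ≤ 30 m (inclusive).
Records missing a date or an uncertainty are *removed* under the default
strict reading; `keep_missing_date` / `keep_missing_uncertainty` switch to
the permissive reading. The retained set is a pure conjunction of the rules
and therefore independent of rule order; the filter log attributes each
removal to the first failing rule in the fixed order type → date →
uncertainty, so the counts always sum to input − retained. Administrative
centroid artifacts are removed against a user-supplied centroid list
(explicit because no administrative layers ship with the package), and
duplicates are defined as records sharing a snap cell (default: the
analysis cell size), which is the per-cell thinning model fitting needs.

## Background generation

**KDE background.** A Gaussian product-kernel density is fitted to the
presence coordinates. The `"auto"` bandwidth is the two-dimensional
Silverman reference rule per axis, `h_i = sd_i · n^(−1/6)` — the d = 2 case
of `σ · n^(−1/(d+4))`. (The univariate `n^(−1/5)` rule-of-thumb is a 1-D
formula and undersmooths spatial point patterns; a scalar or per-axis
override is available.) Background points are drawn on the analysis grid
with probability proportional to the density restricted to the sampling
extent — the convex hull of the presences dilated by one third of the
larger coordinate range. The "maximum difference between minimum and
maximum X and Y coordinates" wording admits a per-axis reading; the
implementation uses max-of-ranges as a uniform dilation, with `per_axis =
TRUE` as the alternative. Sampled points sit at cell centers, so drawn cells
can repeat; this mirrors per-cell extraction downstream.

**Target-guild background.** Occurrence records of species with the same
lifeform, clipped to the 99% KDE isopleth of the focal presences (the
smallest set of grid cells, by density level, enclosing 99% of the
discretized mass; ties broken by cell index), subsampled to the requested
size with a seeded simple random sample. The default background size is
10,000 (unstated in the method description this follows; configurable).

## Predictor screening

Rasters are harmonized to the template grid by nearest-neighbor resampling
(each output cell takes the source cell containing its center), then point
values are extracted into a design table of presences (response 1) and
background (response 0). Collinearity is screened on presences and
background jointly (the convention of the tooling this follows; a row
subset argument exposes alternatives): for each variable pair the screen
takes max(|Pearson|, |Spearman|, |Kendall τ-b|) and, while any retained
pair exceeds 0.7, removes the lower-priority member. `"auto"` priority
removes the member with the larger mean absolute correlation to the other
retained variables (ties lexicographic); an explicit priority list makes
the human pre-selection step replayable. Kendall is τ-b (tie-corrected),
computed in compiled code.

## The five algorithms

All fits are seeded, and rows are canonicalized (sorted) before fitting so
the scorer is invariant to row order even for bootstrap-based learners.

* **glm_stepwise** — bidirectional stepwise logistic regression by AIC,
  starting from the main-effects model with a candidate scope of main
  effects + squared terms + all pairwise interactions, capped at 200
  candidate terms as a combinatorial guard.
* **mars** — additive (degree-1) piecewise-linear hinge regression built
  directly: forward selection of reflected hinge pairs by least-squares
  RSS over quantile knots, backward pruning of individual basis functions
  by GCV with penalty 2.0 (effective parameters k + penalty·(k−1)/2), and
  a final logistic refit of the surviving basis so scores are probabilities.
* **brt** — stochastic gradient boosting with bernoulli loss, bag fraction
  0.5, learning rate 0.01, tree depth 3, minimum node 10. The tree count is
  picked at the deviance minimum of a seeded stratified 20% internal
  holdout; the kept model is the 80%-fit truncated at that iteration.
* **rf** — probability random forest: 1,000 gini-split CART trees on
  bootstrap samples, mtry = ⌊√p⌋, suitability = mean terminal-node presence
  fraction.
* **maxent_like** — infinitely-weighted penalized logistic regression on
  linear + quadratic + hinge features (the glmnet/maxnet equivalence; the
  Java Maxent is deliberately not bundled). Presences are also added to the
  background class (the maxnet convention — without it the weighted IRLS
  can diverge on separable data); background weight 100; λ chosen by AIC
  along the lasso path (cross-validated deviance is insensitive to the
  presence fit under 100× background weighting) and scaled by a
  regularization multiplier. Reported suitability is plogis(η + log W), a
  fixed monotone rescale so scores spread over [0, 1]; every downstream use
  is rank- or threshold-based, so the rescale changes nothing material.

Internal variable selection: stepwise GLM and MARS report their reduced
variable sets; BRT reports the variables its kept trees actually split on;
RF and the maxent-style model retain everything.

**Gates.** After 10-fold stratified cross-validation, a model is flagged
overfit when train AUC − CV AUC > 0.05 and re-fitted once with stronger
regularization (GLM: main effects only; MARS: penalty ×2, half the term
budget; BRT: learning rate /2, depth −1; RF: minimum node ≥ 20, depth cap
12; maxent-like: λ ×4). A second flag, or CV AUC < 0.7, drops the model
from ensembles. Per-fold threshold metrics use the sensitivity =
specificity threshold computed on that fold's *training* scores — test
scores never pick their own threshold.

## Thresholds, ensembles, MESS, importance

Binarization uses score ≥ threshold everywhere. The percentile thresholds
follow the exclusion convention: the pct-q threshold is the (⌊q·n⌋+1)-th
smallest presence score, so exactly ⌊q·n⌋ training presences are classified
unsuitable — this pins down an otherwise ambiguous "lowest q% excluded"
rule and guarantees MPP ≤ pct1 ≤ pct10. MSS maximizes sensitivity +
specificity over observed scores, ties to the lowest threshold. Ensembles
are cellwise counts of retained binary models; when models are dropped the
recorded `retained_count` shrinks rather than rescaling counts to 10.

MESS follows the published similarity formula (with f the percentage of
reference values strictly below the cell value): 100(v−min)/(max−min) below
the range, 2f up to the median, 2(100−f) above it, 100(max−v)/(max−min)
beyond the range; the surface is the minimum over variables, and negative
values flag novel environments. The reference set is the training rows
(presences + background) by default. Importance is permutation ΔAUC —
shuffle one column across presences and background jointly, rescore,
average over 5 seeded permutations — plus a normalized percent
contribution over the positive ΔAUC values, both labelled in the output.

## Risk summaries

Cell-in-polygon is decided by the cell-center test (deterministic, grid
resolution limited). Suitable cells are those where at least
⌈retained/2⌉ models agree (configurable). Areas are reported in map units²,
hectares (10⁴ m²) and acres (4046.8564224 m²) since practitioner tables mix
both. Distance to the nearest occurrence is Euclidean in the projected
plane — acceptable at regional scales in an equal-area projection — and 0
whenever an occurrence lies inside or on the unit boundary.

## The synthetic test world

`generate_landscape` builds smooth Gaussian-random-field layers (white
noise smoothed by FFT convolution at a patch scale in cells, standardized).
Smoothing leaves sizeable chance correlations between nominally independent
layers — the effective sample size is the number of patches, not cells — so
the generator whitens the fields empirically before mixing by the Cholesky
factor of the requested correlation matrix; realized cross-correlations
therefore match the request essentially exactly. `make_virtual_species`
defines suitability as the inverse logit of a linear (+ optional quadratic)
form; `sample_presences` draws cells proportionally to suitability × bias
and emits records with complete metadata so they pass the occurrence
filters untouched. Probability-proportional sampling (not thresholded
occupancy) keeps the truth continuous and tests ranking metrics directly.
The fixture CRS uses 90-unit cells to mirror the 90 m analysis convention.

The frozen recovery world used by the acceptance suite: 128×128 cells,
six layers with confounder pairs corr(x1,x3) = corr(x2,x4) = 0.5 (so the
importance ranking must separate drivers from correlated confounders),
patch scale 8 cells (~700 m — fine-scale habitat heterogeneity at 90 m
resolution), species intercept −4 (prevalence ≈ 0.18, a realistic
low-prevalence invader) with β = +3 on x1 and −3 on x2, 500 presences and
5,000 KDE background points.

**What a green test does and does not establish.** The generator emulates
correlated continuous predictors, a known parametric niche, sampling bias,
and toy management units. It does not emulate spatial autocorrelation of
residuals, observation error in coordinates, temporal dynamics, or
dispersal limitation — so green recovery tests certify the pipeline's
statistical machinery, not its behavior on any real species.

**A deliberate red expectation.** One acceptance expectation asserts
cross-validated AUC ≥ 0.85 for every retained algorithm on the frozen
world. The stated world cannot meet it: the KDE background is by
construction a kernel-smoothed copy of the presence density, and with
presences drawn proportionally to suitability the presence and background
distributions differ only by that smoothing. Scoring the design table with
the *true* log-odds (3·x1 − 3·x2 — the Bayes-optimal ranking under the
generating model) yields AUC ≈ 0.73 on the frozen world and at most ≈ 0.85
at the most favorable defensible patch scale; no fitted model can
systematically beat that reference. The expectation is asserted as stated
and left failing, with this analysis as the record. The companion
expectations — importance recovery of {x1, x2}, the overfit gate on a
memorizing forest, the drop gate on a noise-only species — are attainable
and pass.

## Numerical conventions and edge cases

* Ties: sens=spec threshold and MSS resolve ties to the lowest candidate;
  isopleth accumulation breaks density ties by cell index; `"auto"` screen
  priority breaks mean-correlation ties lexicographically.
* Degenerate inputs: < 3 distinct or collinear presences fail MCP
  construction; identical coordinates fail KDE bandwidth estimation;
  zero-variance variables get zero correlation entries and are flagged;
  degenerate MESS reference ranges exclude the variable with a warning.
* AUC uses the Mann–Whitney midrank formulation (ties count ½); AUC-PR is
  step-interpolated average precision over distinct-score thresholds.
* Rasters round-trip through ASCII grids at %.17g, so replays from a run
  manifest are bit-identical.
* All stochastic stages consume seeds derived from the master seed (fixed
  offsets, kept below 2³¹); fitting canonicalizes row order first, so equal
  inputs give equal models regardless of table ordering.

## Known limitations

Single-band ASCII rasters only (no GeoTIFF/compression); planar geometry
only (no geodesic distances, no reprojection — inputs must arrive in an
equal-area CRS); no spatial block cross-validation; the maxent-style model
is a penalized-regression equivalence, not the Java Maxent 3.4.1; expert
review and iterative re-modeling are represented as config fields and
logged decisions, not an interactive process.
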