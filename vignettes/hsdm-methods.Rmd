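---
title: "Hierarchical habitat modelling with hsdm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical habitat modelling with hsdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsdm)
```

## The modelling problem

`hsdm` models the wintering habitat of a wetland bird at two nested
spatial scales and combines the two predictions hierarchically:

* a **coarse "national" model** relates thinned occurrence points to
  macroclimate (bioclim-style variables: isothermality `bio3`, mean
  temperature of the driest quarter `bio9`, precipitation of the driest
  month `bio14`, precipitation seasonality `bio15`) and land cover, and
  is the only model projected onto future climate scenarios — a model
  calibrated on a small region sees a truncated climatic niche and
  extrapolates badly, so projection is reserved for the scale that
  samples the full niche;
* a **fine "provincial" model** relates locally collected occurrences to
  local conditions (elevation, slope, aspect, night-time lights, distance
  to roads, distance to water, land cover). Its futures swap only the
  land-cover layer for maps simulated by a cellular automaton; climate
  layers are deliberately absent;
* the **final habitat map** is the cellwise intersection of the
  binarized coarse (climatically suitable) and fine (locally suitable)
  maps, carrying the fine-scale suitability values inside the overlap.

Because real occurrence and climate archives are not bundled, the
package ships a synthetic-data generator with a *known* logistic
suitability truth. Every downstream claim the test suite makes —
held-out discrimination, optimum recovery, importance attribution, CA
agreement, area accounting — is checked against that planted truth.

## The ensemble and its weighting

Six presence-background learners are fitted per scale behind one
interface (`fit_member()`): logistic regression with linear and
quadratic terms (GLM), spline logistic regression (GAM, via `mgcv`),
lasso-penalized logistic regression on hinge + quadratic features in the
maxent tradition (MXD, via `glmnet`), a probability random forest (RDF,
via `ranger`), gradient-boosted trees (BRT, via `xgboost`), and a
radial-kernel SVM with Platt calibration (SVM, via `e1071`). These are
faithful family stand-ins, not wrappers of any particular legacy
toolchain; the contract is "seeded probabilistic binary learner with
predictions in [0, 1]".

`fit_ensemble()` repeats an 80/20 stratified split `n_runs` times
(default 10), evaluates every member on each held-out fold, and averages
each member's True Skill Statistic over the runs. The ensemble weight of
member $j$ is

$$W_j = \frac{r_j}{\sum_{j=1}^{h} r_j},$$

with $r_j$ the member's mean TSS and $h$ the number of members. Members
with $r_j \le 0$ carry no skill under this scheme and are excluded
before normalization (a negative weight would invert a model's map).
The final members are refit on all data and the ensemble map is the
cellwise weighted mean, so it is bounded by the member maps. The
weighting is applied over the six per-algorithm models (TSS = run mean),
not over all run-models; `ensemble_auc` additionally reports the
held-out AUC of the weighted blend itself, computed by applying the
final weights to each run's test-fold member predictions.

## Evaluation metrics

`evaluate_scores()` reports seven presence-background metrics: rank AUC
(Mann–Whitney, ties counted ½), Kappa, TSS, Jaccard, Sørensen, Fpb and
the continuous Boyce index, plus the MTSS threshold. Design points:

* **MTSS** scans the unique observed scores, maximizes sensitivity +
  specificity with the inclusive rule `score >= threshold`, and breaks
  ties toward the smallest threshold. It is computed on *training*
  scores (the "T" in the name) and is equivariant under strictly
  increasing transforms.
* **Boyce** uses 101 overlapping windows of width 10 % of the combined
  score range — the common settings for the continuous variant — drops
  windows with zero expected (background) fraction, and is the Spearman
  correlation between predicted-to-expected ratios and window midpoints.
  Fewer than three valid windows yields `NA`, never a number.
* **Fpb** is implemented as the F-measure on presence-background counts,
  $2TP/(2TP+FP+FN)$, with background standing in for absences; with
  that design it coincides numerically with Sørensen, and only its range
  and perfect-case value are externally constrained.
* Empty confusion margins yield `NA` ("undefined"), not 0.
* **Permutation importance** permutes each conceptual predictor
  (indicator columns of a categorical layer are permuted jointly with
  one shared permutation), averages the AUC drop over `n_reps`
  permutations, clips negatives to zero and normalizes per algorithm to
  sum to 1; the cross-algorithm mean is the reported aggregate.
* **Response curves** use the evaluation-strip method: sweep one
  variable over its observed range with every other column held at its
  median. The reported peak (`argmax`) is read off a lightly smoothed
  copy of the curve (running mean, 5 steps by default): tree members
  produce piecewise-constant strips whose raw argmax sits on plateau
  edges about a degree wide, which is an unstable estimator of a thermal
  optimum. The returned curve itself is unsmoothed, and `smooth_window
  = 1` restores the raw rule.

## Land-use change simulation

The land-use module is a deliberately simplified analogue of
patch-generating land-use simulators:

* `estimate_demand()` extrapolates per-class cell counts linearly from
  the historical pair ("the transition rate stays what it was"),
  clamps at zero and rescales by largest-remainder rounding so demand
  sums exactly to the cell count.
* `fit_transition_model()` (the expansion-analysis step) takes, per
  class, the cells that changed *into* the class as positives and an
  equal-sized seeded sample of unchanged cells as negatives, and fits a
  probability random forest on driver values. The resulting surface uses
  out-of-bag probabilities at the training cells — refit probabilities
  there are memorized near 0/1 and would paint an overfit halo around
  the historical expansion ring.
* `simulate_lulc()` allocates conversions iteratively: a donor cell's
  probability of converting to growing class $c$ is
  $OP_c = P_c\,(w\,N_c + (1-w))$ with $N_c$ the class fraction in the
  3×3 Moore neighbourhood and $w = 0.9$; cells with $N_c = 0$ may still
  seed a new patch with probability 0.01 per sweep, driven by $P_c$
  alone. Candidates are drawn by roulette wheel, donors never drop below
  their own demand, and the acceptance threshold decays by 0.9 per
  sweep. Two numerical guards matter in practice: $P_c$ is floored at
  $10^{-6}$ so the roulette stays defined where the learned surface is
  exactly zero (a random forest votes 0 beyond its training ring), and
  when no candidate clears the decayed threshold the roulette weights
  alone decide — otherwise demand beyond the historical ring could never
  be allocated. Default convergence tolerance is ±1 % of the cell count;
  cell count is conserved at every step by construction.
* `map_agreement()` validates a simulated map against the truth with
  overall accuracy and multi-class Kappa.

These defaults (w, decay, seeding rate, tolerance) are engineering
choices of this implementation, not constants inherited from any
specific simulator.

## The synthetic study system

All generators are pure functions of (parameters, seed):

* **Climate fields.** `bio9` is a linear south–north gradient (south
  +20 °C, north −15 °C) plus smooth correlated noise (Gaussian-filtered
  white noise, kernel σ = 4 cells, amplitude 1.5 °C); `bio14` is a
  smooth field on [0, 100] mm; `bio3`/`bio15` are smooth nuisance fields
  that the truth never uses — their fitted importance is the package's
  negative control.
* **Truth model.** Suitability is the inverse logit of an additive
  predictor. The `bio9` term is built from an optimum (default 0 °C) and
  a curvature (default 0.15 logit/°C²) chosen so suitability is
  effectively zero more than ~6–7 °C from the optimum — the sharp
  thermal window typical of a wintering wader; `bio14` enters linearly
  (0.06 logit/mm) so dry cells are unsuitable. The provincial truth adds
  an exponential distance-to-water decay (e-folding 2500 m at the 300 m
  reference resolution) and per-class land-cover weights with wetland
  highest (1.0), impervious intermediate (0.6) — rivers and urban
  riverbanks are usable, bare land is not.
* **Land cover.** A smoothed-field argmax mosaic, biased toward cropland
  and grassland so the conversion rule has material to act on, with an
  impervious seed patch at the urban centre. The known rule converts
  grassland within distance *d* of the centre to impervious, with *d*
  growing linearly per step; the rule parameters are returned so tests
  can recompute conversions independently.
* **Scenarios.** Temperature deltas +0.5/+1.0/+1.5 °C (2030s) and
  +0.8/+1.5/+2.5 °C (2050s) for the optimistic/moderate/pessimistic
  scenario families, with mild precipitation factors; the deltas are
  ordered stand-ins, not downscaled model output.
* **What the generator does not emulate:** observation bias and spatial
  clustering of surveys, interactions among climate variables,
  subpixel mixed land cover, realistic GCM spatial anomaly patterns.
  Passing tests therefore demonstrate the *machinery* is correct and
  recovers planted structure; they do not certify performance on real
  archives.

## Geometry and areas

Rasters live on regular grids with row 1 northernmost; a cell owns its
top and left edges, which removes boundary ambiguity in point-in-cell
tests and nearest-neighbour resampling (done by cell-centre lookup).
Two coordinate modes are supported: a flat equal-area mode (exact areas,
used wherever tests need exact arithmetic) and a lon/lat mode whose cell
areas use the standard cosine-of-latitude spherical approximation — the
area convention of the emulated analysis is not externally fixed, so
both modes are provided. Latitudinal profiles aggregate suitable area
into half-open 0.1° bands aligned to multiples of the bandwidth; tied
peaks resolve to the southernmost band. I/O uses ESRI ASCII grids
extended with `kind` and `crs` header keys, round-tripping bit-exactly;
nodata propagates through all map algebra and never counts as suitable.

## Pipeline study sizes

The default configuration runs the national stage on a 70 × 60 grid of
0.2° cells (lat 28–42 °N) and the provincial stage on a nested 160 × 120
grid of 0.05° cells, with 400/400 and 300/300 presence/background points
and 5 evaluation runs — sizes chosen so a full hierarchical run
completes in well under a minute on one CPU while every stage still has
estimable signal. The recovery experiments in the acceptance material
use 500 presences, 500 background points and 10 runs. Distance-based
parameters in the pipeline configuration (water-decay 15 km, urban
growth 100 km) are scaled to the ~5.6 km cells of that demonstration
grid; module-level tests use the 300 m reference resolution with the
2500 m water decay.

## Known limitations

* Collinearity screening is greedy (iteratively dropping the member of
  the worst pair with the larger mean |r|); it does not guarantee the
  globally largest surviving set, and an "ecologically meaningful"
  keep-list overrides it by construction.
* The CA is a single-resolution allocator without planning or policy
  constraint masks; demand feasibility is the caller's contract.
* The MXD member implements hinge + quadratic features only, a compact
  subset of the classic maxent feature zoo.
* Lon/lat areas use the cosine approximation, adequate at the mid
  latitudes modelled here; no general projection engine is included.
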