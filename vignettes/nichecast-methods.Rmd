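---
title: "Methods: maximum-entropy niche modelling with nichecast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy niche modelling with nichecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## The model

`nichecast` estimates relative habitat suitability for a species from
presence-only occurrence records contrasted against background (landscape)
samples — the presence-background setting in which true absences are
unavailable. The core is a maximum-entropy density estimator: among all
distributions over the background landscape, it selects the one of maximum
entropy subject to (soft) constraints that feature expectations match their
presence-sample averages. Equivalently, it minimizes the L1-penalized
negative log-likelihood

$$
L(\beta) \;=\; -\frac{1}{m}\sum_{i=1}^{m} \eta(x_i)
\;+\; \log \sum_{j} w_j\, e^{\eta(z_j)}
\;+\; \sum_k \lambda_k\,|\beta_k|,
\qquad \eta = \beta^\top f,
$$

where $x_i$ are the $m$ presence samples, $z_j$ the background samples with
normalized weights $w_j$, and $f$ the feature basis expanded from the raw
environmental variables. The **regularized training gain** is
$G = L(0) - L(\hat\beta) \ge 0$: the penalized log-likelihood improvement
over the uniform (null) distribution, reported in the same units the
jackknife importance test uses.

### Feature classes

Variables are rescaled to $[0,1]$ by their background minimum and maximum.
Five feature classes are available: linear, quadratic, pairwise product,
threshold (step indicator above a knot) and hinge (forward and reverse
piecewise-linear ramps). Knots sit at equally spaced background quantiles
(20 per variable by default; the tests and example pipeline use 6–10, which
is ample at desk scale). With `autoFeatures` on, class availability follows
the conventional presence-count cutoffs: quadratic from 10 presences, hinge
from 15, threshold and product from 80.

### Regularization

Each feature's penalty is $\lambda_k = RM \cdot \rho(\text{class}_k)\cdot
s_k/\sqrt{m}$ with $s_k$ the feature's background standard deviation and
$\rho$ the published per-class base constants (piecewise-linear in $m$ for
linear/quadratic/product and threshold; constant 0.5 for hinge). $RM$, the
regularization multiplier, defaults to 1. These defaults are implemented
from their published definitions, not bit-matched against any particular
implementation.

### Optimizer

Training is cyclic coordinate descent with an exact soft-threshold Newton
step per coordinate and backtracking, so every accepted update strictly
decreases the penalized objective; after each dense pass the optimizer
iterates over the active (nonzero) set until it stabilizes. This
coordinate-wise scheme is what makes **percent contribution** well defined:
every accepted update's gain increase is credited to the updated feature's
source variable (split equally for products), and the accumulated ledger is
normalized to 100%. A full-gradient method would have no such per-variable
attribution. Convergence is declared when a dense pass improves the
penalized gain by less than `tol` (default 1e-6); the per-pass gain trace
is stored in the model and is non-decreasing by construction.

### Output transforms

With $q(z) = e^{\eta(z) - \log Z}/n_{bg}$ the raw relative occurrence rate
(summing to 1 over the training background) and $H$ the entropy of the
fitted background distribution, the cloglog output is
$P = 1 - \exp(-e^{H} q)$ and the logistic output $P = e^{H}q/(1 + e^{H}q)$.
Cloglog is the default, being the modern convention; the transform label is
recorded in every map. At projection time variables are clamped to their
training ranges by default, preventing feature extrapolation under novel
(e.g. warmed) climates.

## The analysis pipeline

`runPipeline()` reproduces a complete niche-modelling study in a fixed
order: occurrence cleaning, an initial model on all variables, variable
selection, a final model, evaluation, thresholding, classification and
scenario projection.

**Occurrence preparation.** Exact coordinate duplicates are collapsed;
records off-grid or on nodata cells are removed (never "repaired" — the
nodata mask serves as the land/validity proxy); and the set is spatially
thinned to at most one record per analysis cell, the within-cell survivor
chosen uniformly under a seed. Thinning is idempotent and its one-per-cell
criterion is applied on the analysis grid directly (a distance-based mode is
deliberately out of scope). A Gaussian kernel density of the presence cell
centers (Silverman's rule bandwidth per axis, rescaled to maximum 1) serves
as a sampling-bias surface from which background cells are drawn — 10,000
by default, the conventional presence-background choice.

**Variable selection.** Pearson correlations are computed at the presence
records only. The two-stage rule then drops any variable that has
$|r| > 0.7$ with *some* strictly higher-contribution variable — an
all-pairs, simultaneous rule, hence independent of variable order — and
afterwards drops survivors contributing $\le 1\%$. Three conventions
matter and are guarded by regression tests: the comparison uses $|r|$, not
signed $r$; both thresholds are strict; and elimination is simultaneous
rather than greedy-sequential. With the packaged worked-example tables,
greedy processing or signed comparison each produce a different (wrong)
kept set. An exact contribution tie inside a violating pair raises an error
when (and only when) it would decide a variable's fate; silent tie-breaking
would be invisible nondeterminism.

**Evaluation.** "k-repeat cross-validation" is read as k-fold
cross-validation of the presences (the replicate semantics of the standard
maxent tool): the background is shared across folds, each fold's model is
scored on its held-out presences against the background with the rank-based
(Mann–Whitney) AUC, and the mean and standard deviation are taken across
folds. Out-of-fold presence scores and per-fold background scores are
pooled for thresholding. The jackknife importance test refits per variable
with-only and without models per replicate and averages the regularized
gains. Response curves vary one variable over its background range while
fixing the others at their presence-sample means ("sample" in the maxent
idiom means presence samples; this is configurable).

**Thresholding and classification.** The suitability threshold is the
smallest candidate score maximizing sensitivity plus specificity (MTSPS) on
the pooled out-of-fold predictions — one threshold per model, matching how a
single published threshold value is reported; the smallest-maximizer
tie-break is deterministic and inclusive (larger suitable area), the
conservative choice for pest surveillance. Maps are partitioned into four
classes with left-open/right-closed boundaries: unsuitable $P \le t$, low
$t < P \le 0.4$, medium $0.4 < P \le 0.6$, high $P > 0.6$. If $t \ge 0.4$
the low class is structurally empty; this is permitted and logged.

**Scenario projection.** Altered-climate stacks are built by shifting
temperature-like bands additively and scaling precipitation-like bands
multiplicatively; projection uses clamping by default and class-change
accounting reports the full 4x4 transition matrix, which conserves cell
counts by construction.

## The synthetic study world

Because real occurrence databases and global climate rasters are external
resources, the package carries a generator that emulates their structure.
Smooth fields (white noise convolved with a Gaussian kernel) are whitened
and mixed through a Cholesky factor so the empirical inter-band
correlations match a target matrix; the achieved matrix is returned because
floor-clamping (precipitation at 0) perturbs it slightly. The default world
is 100 x 100 cells with a ~4% nodata border frame and eight bands.

A niche is planted on three bands, mirroring the response shapes a
subtropical insect pest exhibits: a **plateau** response on cold-quarter
temperature (suitability 1 on 15–25 degrees, with Gaussian tails of width
20% of the plateau span — field response curves constrain the shape, not a
formula, so the tail form is a package choice), a **peaked** Gaussian
response on wettest-month
precipitation (optimum 200 mm, width 150 mm), and a **saturating** response
on driest-month precipitation (exactly 0 at zero rainfall, a smooth
squared-sine rise to 1 at 50 mm, flat beyond). The band means and spreads
are chosen so the planted niche sits in the distributional tail (mean true
suitability about 0.1): that is the realistic analogue of a worldwide
suitability surface for a tropical/subtropical pest, where most of the
globe is too cold or too dry. Presences are drawn without replacement with
probability proportional to suitability (times an optional bias surface),
one record per drawn cell center.

What the generator does *not* emulate: spherical geometry and area
weighting, spatially structured nodata (oceans), monthly climatologies
behind the derived variables, and observation error in coordinates. Passing
tests on this world therefore demonstrate the correctness and calibration
of the algorithms, not field performance on real data.

## Numerical choices and degenerate inputs

* Grid convention: row 1 is the northernmost row; cells are half-open
  $[edge, edge + cellSize)$; a point on a cell's west/north edge belongs to
  that cell. The ESRI ASCII grid dialect is written at full double
  precision, so write/read round trips are exact.
* Constant variables expand to a zero feature with a warning and an
  effectively infinite penalty (never updated). Feature standard deviations
  below 1e-3 are floored at 1e-3 in the penalty to keep $\lambda$ bounded
  away from zero.
* The coordinate update curvature is floored at 1e-10; backtracking halves
  the step at most 25 times and an update is only accepted on strict
  decrease, which is what makes the gain trace monotone and $G \ge 0$
  exact.
* Model JSON is written at 17 significant digits, so a reloaded model
  reproduces predictions bit for bit.
* One master seed drives the pipeline; each stage derives its own seed by
  hashing the stage label, so enabling or disabling one stage never shifts
  another stage's random stream.

## Problem sizes used in the checks

The packaged checks run the worked-example selection on the shipped 20 x 20
correlation and contribution tables (deterministic, instantaneous); engine
oracles on instances of up to a few dozen samples against dense grid
searches; discrimination and parameter-recovery checks on the default
100 x 100 world with 300 sampled presences, 2,000 background cells, 10
knots per variable and 10-fold cross-validation over 10 seeds; and the full
pipeline end-to-end twice at that same scale (with 5 jackknife replicates)
to verify byte-identical artifacts. These sizes are the package's standard
desk-scale testbed; all are configurable upward.

## Known limitations

* Only the ESRI ASCII grid raster format is supported; no reprojection or
  resampling between coordinate systems is performed, and all layers must
  share one grid exactly.
* AUC on presence-background data is a relative, not absolute, measure:
  its ceiling depends on the prevalence of suitable habitat, and values are
  not comparable across differently constructed backgrounds.
* Percent contribution is path-dependent (it reflects the optimizer's
  update history) and is best read alongside the jackknife gains, which are
  refit-based.
* Cross-validation partitions presences at random; spatially blocked
  validation is out of scope.
* The published per-class regularization defaults are followed, but exact
  numeric agreement with other maxent implementations is not a goal.
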