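---
title: "Models and methods behind xylemclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind xylemclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

xylemclim studies how conifer xylem anatomy responds to its environment
through two routes: directly, via seasonal climate during ring formation,
and indirectly, via the tree's accumulated height (conduit widening makes
lumen dimensions track the hydraulic path length). The package covers the
whole chain from raw measurements to inference: ring-width series become
annual stem diameters and heights; per-tracheid measurements become
earlywood/latewood trait chronologies; monthly climate becomes seasonal
predictors; and a mixed model with autocorrelated, heteroscedastic errors
ties them together, with counterfactual predictions to separate the two
routes.

## Height and diameter reconstruction

A tree cored at height $h_0$ with measured sampling DBH and height anchors
a per-year reconstruction. Annual DBH is obtained by cumulatively
subtracting double ring widths backwards from the sampling DBH
(`reconstruct_dbh()`). Height is then interpolated linearly in DBH
(`interpolate_height()`):

$$h_{it} = h_{i0} + a_i \cdot \mathrm{DBH}_{it}, \qquad
  a_i = \frac{h_i^{\mathrm{samp}} - h_{i0}}{\mathrm{DBH}_i^{\mathrm{samp}}},$$

so that the curve passes exactly through both anchors: the coring height
at hypothetical DBH $= 0$ and the measured height in the sampling year.
The linearity assumption is adequate for trees still on the rising leg of
their height-diameter curve; it will underestimate early heights for trees
near their asymptote.

Missing (locally absent) rings are imputed as the arithmetic mean of the
pooled up-to-10 nearest measured ring widths on each side
(`impute_missing_rings()`). Two deliberate choices: at series ends the
shorter side contributes whatever it has (graceful degradation rather than
failure), and imputed values never feed other imputations, so runs of
consecutive missing rings are filled jointly from measured neighbors only
and the result is independent of fill order.

Because imputed widths can overshoot the deleted rings, a series whose
sampling DBH equals the cumulative double ring width exactly can come out
marginally "too wide". `reconstruct_dbh()` therefore clamps shortfalls of
up to `slack_cm` (default 1 cm) to a DBH of 0 with a warning and treats
anything larger as genuinely inconsistent input (error). Units are fixed
throughout: ring widths mm, diameters cm, heights m.

## Site allometry and ontogeny

Height-diameter relationships are summarized per site with the modified
Weibull curve

$$h = h_{\max}\, e^{a\,\mathrm{DBH}^{b}},$$

fitted by Levenberg-Marquardt least squares (`fit_weibull()`, via
minpack.lm) with a data-driven start and a deterministic 20-point
multistart fallback. A note on the exponents: a curve that *rises* from 0
toward the asymptote $h_{\max}$ requires $a < 0$ together with $b < 0$ —
the exponent $a\,\mathrm{DBH}^b$ must decay to zero as DBH grows. With
$b > 0$ the same expression is monotonically decreasing. The fitter
therefore leaves the sign of $b$ free and the synthetic sites use
$a < 0,\ b < 0$; the starting value for $b$ is chosen from the sign of
the height-diameter correlation.

The expected ring width as a function of cambial age (the regional curve,
`fit_regional_curve()`) is the age-wise mean smoothed by a cubic smoothing
spline whose effective degrees of freedom are `1/span` (default
`span = 0.1`, i.e. a bandwidth of 10% of the maximum age; `span = 0`
keeps raw means, `span = Inf` is the global mean). Doubling the cumulative
curve gives the mean diameter-age trajectory, and composing it with the
Weibull fit gives the site's age-diameter-height ontogeny
(`ontogenetic_trajectory()`); raw cumulative sums are used without bias
correction.

## Cell-level traits and chronologies

Per tracheid (`build_chronology()` computes all of these and averages):

* **Mork's index**: $MI = 4\,\mathrm{CWT_{rad}} / \mathrm{LD_{rad}}$; a
  cell is latewood when $MI \ge 1$ — the classical "double double wall
  meets or exceeds the lumen" criterion. The boundary case goes to
  latewood, and the radial lumen diameter is the default basis; both
  choices are configurable (`boundary`, `diameter = "mean"`) because the
  literature varies on them.
* **Conduit reinforcement** $TB^2 = (2\,\mathrm{CWT}_s / B_s)^2$ with side
  $s$ the one with the *smaller* single wall thickness and $B_s$ the
  length of that same wall; ties resolve to the radial side,
  deterministically.
* **Anatomical density** $\mathrm{DEN} = \mathrm{CWA} / (\mathrm{CWA} +
  \mathrm{LA})$, the wall-area share of the total cell area (tracheids
  only; cells flagged non-tracheid are dropped up front).
* **CWT** is the mean of the radial and tangential single-wall
  thicknesses.

Annual values are unweighted means over the cells in each tree x year x
portion group, matching the "annual means of a per-cell trait" reading;
DEN can alternatively be computed as a ratio of sums
(`den_method = "ratio_of_sums"`) for sensitivity checks — the two differ
whenever cell sizes vary within a ring. Groups without cells simply do
not appear in the chronology.

## Seasonal climate

Ring year $y$ is explained by previous fall (Sep-Nov of $y-1$), previous
winter (Dec of $y-1$ - Feb of $y$), spring (Mar-May) and summer
(Jun-Aug). Temperature aggregates by the mean. For precipitation the
seasonal statistic is the *sum* of the monthly sums, the dendroclimatological
convention; a mean option exists and differs only by a constant factor of
3, which the later z-scoring absorbs entirely. A ring year enters the
analysis only when all twelve contributing months are present; when years
are requested explicitly, gaps are an error that names the missing
months.

## The mixed model

Each trait x ring-portion combination is modeled independently (8 models).
$TB^2$ and CWT are natural-log transformed first (right-skewed,
multiplicative errors), then response and all numeric predictors are
z-scored globally (mean 0, SD 1) so effect sizes are comparable across
traits; height and squared height are standardized separately after
squaring. For tree $i$ in year $t$:

$$y_{it} = \mathbf{x}_{it}^\top \beta + b_{0i} + b_{1i} h_{it} +
  b_{2i} h_{it}^2 + \varepsilon_{it}$$

* **Fixed effects** (29 for 3 sites): intercept, 2 site indicators
  (reference site first), $h$, $h^2$, 8 seasonal predictors, and the 16
  site x climate interactions.
* **Random effects**: per-tree intercept and slopes on $h$ and $h^2$ with
  *diagonal* covariance $D = \mathrm{diag}(\sigma_0^2, \sigma_1^2,
  \sigma_2^2)$.
* **Errors**: continuous-lag AR1 within tree,
  $\mathrm{cor}(\varepsilon_{it}, \varepsilon_{is}) = \phi^{|t-s|}$, so
  that years dropped earlier in the pipeline widen the lag instead of
  corrupting adjacency; plus one relative residual SD per tree (the first
  tree fixed at 1 for identifiability).

Estimation is restricted maximum likelihood. The implementation profiles
the fixed effects (generalized least squares) and the residual variance
out of the criterion, leaving an unconstrained parameter vector of 3 log
random-effect SDs, the Fisher-z of $\phi$ and $m-1$ log relative SDs.
Because the AR1 process is Markov, the inverse of each tree's correlation
matrix is tridiagonal with closed-form entries, and the low-rank random
effects fold in through the Woodbury identity on a 3x3 system — each
likelihood evaluation is linear in the number of observations. The
optimizer is bounded quasi-Newton (L-BFGS-B) on the transformed scale
(bounds log-SD in [-8, 4], Fisher-z in [-5, 5]); five deterministic
jittered starting points are evaluated first, the search runs from the
best of them and falls back to the others on non-convergence. Running
full optimizations from every start would multiply the cost roughly
fivefold for identical coverage of the start region, so the package
evaluates first and optimizes once. Variance components that run to the
lower bound are reported with a `boundary` flag rather than erroring.

Wald t tests use a two-level denominator-df heuristic in the style of
hierarchical-model software: terms constant within trees (intercept,
site) get $m - p_{\mathrm{outer}}$ df; within-tree terms get
$N - m - p_{\mathrm{inner}}$. This is a documented convention, not an
exact small-sample distribution; `df_method = "normal"` switches to z
tests. Stars follow the usual thresholds (0.05, 0.01, 0.001).

Site contrasts (`site_contrasts()`) evaluate marginal means at the mean
(zero) of every standardized covariate — interactions then vanish and a
site mean is just intercept + offset — and adjust pairwise p-values with
the studentized-range distribution at the between-tree df, summarized by
a compact letter display.

Counterfactual predictions (`counterfactual_predict()`) re-predict every
observation with either height (and $h^2$, including their random-slope
shares) or summer temperature (including its site interactions) set to 0.
Predictions are tree-conditional by default — fixed effects plus BLUPs —
because the point of the exercise is to strip one driver from otherwise
individual trajectories; `conditional = FALSE` gives population-level
predictions. The difference between full and held predictions is an exact
linear identity in the held terms, which the tests verify to machine
precision.

## The synthetic-data generator

The generator exists so that every stage has known ground truth without
any field data. It emulates three treeline sites — warm-dry (`W-D`, the
reference), cold-dry (`C-D`), cold-moist (`C-M`) — with 6 trees each,
~80 rings per tree ending in 2015, and stylized continental boreal
monthly climate normals. These sizes are the package's standard study
design and are what the validation studies use. Key mechanics:

* Ring widths follow a negative-exponential cambial-age trend with
  lognormal noise; missing rings are deleted from the observed series
  (flag kept in the truth output only). Sampling DBH is exactly twice the
  cumulative ring width plus a pith allowance defaulting to 0, so the
  reconstruction stage round-trips to machine precision in tests.
* The trait ground truth lives at the level the model is defined on:
  annual earlywood/latewood means. `trait_truth()` specifies, per trait
  and portion, an intercept, height and height^2 coefficients, 8 seasonal
  climate coefficients (plus optional site-specific ones), site offsets,
  random-effect SDs, an AR1 coefficient and per-tree residual scale
  dispersion, all on the model (possibly log) scale with standardized
  covariates.
* Cells are drawn *around* those annual targets: monotone within-ring
  shape curves (lumen shrinking, wall-to-lumen ratio rising) are
  normalized to mean 1 within each portion, so at zero within-ring noise
  the cell means reproduce the targets exactly. The radial lumen diameter
  is derived from the profile's Mork ratio, which crosses 1 exactly at
  the configured earlywood fraction — the geometry's portion labels are
  therefore recoverable by the classifier by construction, noise or not.
* The default truth encodes the qualitative pattern the model family is
  meant to detect: positive height effects on earlywood lumen area,
  negative on conduit reinforcement, and positive summer-temperature
  effects on latewood wall thickness and density specifically at the two
  cold sites.
* One master seed fans out to per-table substreams (Lehmer sequence), so
  regenerating one table never shifts another.

What the generator does *not* emulate: spatial stand structure,
disturbance (fire, competition), cell-count variation between years,
measurement artifacts of image analysis, or correlated within-ring noise
across traits. Cells-per-ring (40) and within-ring noise (CV 0.1) are
unreported quantities in this literature and the defaults are frankly
arbitrary; they affect only the sampling noise of annual means. Passing
tests therefore demonstrate correctness of the estimators under the
stated generating process, not robustness to every feature of real
micrograph data.

## Validation studies and their sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* restricted-likelihood agreement with a dense-covariance oracle on 20
  random small instances (5 or fewer trees, 8 or fewer years), at 1e-8;
* exact reductions: OLS when all structure is off, closed-form GLS under
  AR1 alone;
* a 50-replicate recovery study at the standard design (18 trees x ~80
  years x 3 sites): per-coefficient bias against Monte-Carlo SEs, Wald
  coverage of the height coefficient, type-I error of a null coefficient
  (50 replicates keep the full suite inside a coffee break; the study
  machinery accepts any count);
* a 50-replicate re-detection study of the injected sign/significance
  pattern across four trait models, fitted on annual-level data where the
  truth lives;
* brute-force oracle agreement of every deterministic stage, and the
  counterfactual linear identity at machine precision.

## Known limitations

* Denominator df are heuristic; p-values near thresholds should not be
  over-read (this mirrors common practice in the field's software rather
  than improving on it).
* The AR1-with-gaps convention treats calendar-year distance as the lag;
  if rings are missing *and* unimputed, that is a modeling choice, not a
  derived fact.
* The linear height interpolation and the global (not per-site)
  standardization are simplifications that fit the sampled trees'
  ontogenetic stage; both would need revisiting for trees near their
  height asymptote or for strongly imbalanced site designs.
* `fit_weibull()` reports residual SD but no parameter standard errors;
  uncertainty on the allometry is out of scope.
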