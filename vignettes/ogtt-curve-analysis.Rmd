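---
title: "Functional data analysis of OGTT glucose curves: models and methods"
author: "ogttfda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional data analysis of OGTT glucose curves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogttfda)
```

# The problem

An oral glucose tolerance test (OGTT) records venous glucose (mmol/l) at
0, 30, 60, 90 and 120 minutes after a standardized 75 g glucose load.
Clinical practice usually reduces the five values to scalar summaries —
the fasting value, the 2-h value, the area under the curve (AUC), or a
rule-based shape index — but different curve trajectories can share the
same summaries. This package treats each subject's test as a *curve*:
the five measurements are smoothed into a continuous function, the
sample of curves is decomposed into orthogonal modes of temporal
variation, and those modes (not the raw points) are the units of
analysis. The intended users are biostatisticians analysing repeated
glucose sampling in cohort studies, particularly in pregnancy where a
later 2-h value defines gestational diabetes (WHO criterion:
2-h glucose ≥ 7.8 mmol/l).

# Measurement model and curve fitting

For subject $i$ the observed values follow
$$y_i(t_j) = x_i(t_j) + \epsilon_{ij}, \qquad \epsilon_{ij} \sim N(0, \sigma^2),$$
with $x_i$ a smooth function on $[0, 120]$ minutes expanded in a cubic
B-spline basis with a knot at each sampling time,
$x_i(t) = \mathbf{c}_i^T\phi(t)$. With five breakpoints and order 4 the
basis has $K = 7$ functions, more than the $J = 5$ observations, so the
coefficients are estimated by penalized least squares:
$$\min_C \; \|Y - \Phi C\|_F^2 + \lambda\, \mathrm{tr}(C^T R\, C),
\qquad R = \int_0^{120} D^2\phi(s)\, D^2\phi(s)^T\, ds .$$
The curvature penalty makes the problem well posed for any
$\lambda > 0$; its null space contains exactly the linear functions, so
$\lambda \to \infty$ recovers each subject's least-squares straight line
and $\lambda \to 0$ approaches the roughness-minimising interpolant.

Numerical choices:

* The Gram matrix $W = \int \phi\phi^T$ and the penalty $R$ are
  assembled by Gauss–Legendre quadrature per knot interval with
  `order + 1` nodes — exact for the piecewise-polynomial integrands, so
  partition of unity and the penalty null space hold to machine
  precision.
* The penalized solve uses the augmented least-squares system
  $[\Phi;\ \sqrt{\lambda}L]$ with $L^TL = R$ and a QR decomposition
  rather than the normal equations, which keeps the fit accurate at
  both extremes of $\lambda$ (the normal equations square the condition
  number and lose ~7 digits near $\lambda = 0$ where $K > J$).
* $\lambda = 0$ with $K > J$ is refused with advice to supply a
  positive value.

**Choosing $\lambda$.** All subjects share one smoothing parameter,
selected by minimising the pooled generalized cross-validation score
$$\mathrm{GCV}(\lambda) = \sum_i \frac{J \cdot \mathrm{SSE}_i(\lambda)}
{(J - \mathrm{df}(\lambda))^2},$$
where $\mathrm{df}(\lambda)$ is the trace of the common hat matrix. A
shared $\lambda$ is the natural choice when every subject has the
identical five-point design — per-curve GCV at $J = 5$ is unstable —
but a per-curve mode is available (`select_lambda_gcv(mode =
"per_curve")`). The search uses 25 log-spaced grid points on
$[10^{-4}, 10^4]$ followed by golden-section refinement between the
neighbouring grid points; it is fully deterministic. Grid points where
$\mathrm{df} \ge J$ (an interpolating smoother, undefined GCV) are
skipped with a warning. On default synthetic cohorts the selected
$\lambda$ lands near the minimiser of the true mean integrated squared
error, which the test suite verifies against generator ground truth.

# Functional principal component analysis

Let $\mu(t)$ be the sample mean curve. Each eigenfunction
$\xi_\kappa(t)$ maximises the variance of the subject scores
$$z_{\kappa i} = \int_0^{120} \xi_\kappa(t)\,\bigl(x_i(t) - \mu(t)\bigr)\,dt$$
subject to $\int \xi_\kappa^2 = 1$ and orthogonality to earlier
components. Because every curve lives in the span of the $K$ basis
functions, the eigenproblem is solved *exactly* in coefficient space:
with centred coefficient covariance $\Sigma_c$, the eigenvectors of
$W^{1/2}\Sigma_c W^{1/2}$ pulled back through $W^{-1/2}$ give the
eigenfunction coefficients. A dense-grid quadrature PCA is kept in the
test suite purely as an independent oracle.

Two conventions are fixed and documented rather than left to the
eigen-solver:

* **Centring.** Scores are computed on curves minus the sample mean, so
  a subject at the mean scores zero on every component. (The defining
  integral is sometimes written uncentred; centred scores are what make
  "score means near zero in the reference population" hold, and are
  used throughout.)
* **Sign.** Each $\xi_\kappa$ is oriented so $\int \xi_\kappa\,dt > 0$;
  if that integral is numerically zero (relative to $10^{-6}$ times the
  norm), so that $\xi_\kappa(120) - \xi_\kappa(0) > 0$; failing both,
  so that $\xi_\kappa(0) > 0$. Under this rule the first component of a
  typical OGTT sample reads as "general level" (high score = uniformly
  high glucose) and the second as an early-versus-late contrast
  ("time to peak").

All $K$ components are computed; downstream analyses retain the first
three by default, which on OGTT-like samples carry ~99% of the
between-curve variance. `summary()` tabulates eigenvalues (= score
variances), proportions and cumulative proportions; `mode_curves()`
produces the standard mean ± SD·eigenfunction display, and
`quartile_panels()` the 3×3 cross-classification of subjects by the
lower/upper quartiles of two score columns.

# Simple summary measures

For comparison with tradition, `ogtt_summaries()` computes per subject:
the five raw values, the trapezoid AUC over the five raw measurements
(mmol·min/l — deliberately *not* the integral of the fitted spline, so
the simple measures stay independent of the smoothing stage), and a
rule-based shape classification. The shape rule compresses the series
into significant directional moves: a move counts when the excursion
from the last accepted turning value reaches 0.25 mmol/l (the empirical
threshold in the curve-shape literature; configurable), and while a
direction persists the turning value tracks the running extreme. Sign
patterns map rise–fall → monophasic, rise–fall–rise → biphasic,
rise–fall–rise–fall → triphasic; anything else — no significant move,
an initial fall, more than four moves — is unclassified. The shape
index is then the 2-h minus 90-min value (mono/biphasic) or the 90-min
minus 60-min value (triphasic), undefined for unclassified curves. The
published rule this reconstructs is specified only by its threshold and
index arithmetic; the exact handling of accumulating sub-threshold
moves and endpoint turning points is our formalisation, and edge cases
may classify differently from the original software.

Correlations between summaries and FPC scores use pairwise-complete
observations, so unclassified subjects drop out of shape-index
correlations only. One-way ANOVA of a summary across BMI categories
uses the standard `lm`/`anova` F test with pooled-SD Bonferroni
pairwise comparisons.

# Functional ANOVA

Group mean curves are compared under the reference-coded model
$$x_{lg}(t) = \beta_{\mathrm{ref}}(t) + \beta_g(t) + \epsilon_{lg}(t),$$
with $\beta_{\mathrm{ref}}$ the reference-category mean curve and
$\beta_g$ the category-g contrast, estimated in coefficient space and
evaluated on a 1-minute grid (121 points). The point-wise statistic is
the conventional one-way F ratio — between-group mean square over
within-group mean square at each $t$. Inference is by permutation of
whole-curve labels: with $B$ permutations (default 1000),
$$p(t) = \frac{1 + \#\{b : F_b(t) \ge F(t)\}}{B + 1}, \qquad
p_{\mathrm{overall}} = \frac{1 + \#\{b : \max_t F_b \ge \max_t F\}}{B + 1}.$$
The add-one convention avoids zero p-values; both quantities are
bounded below by $1/(B+1)$. Permutations are seeded and bit-reproducible.
Confidence bands are point-wise normal-theory intervals
$\beta_g(t) \pm z_{1-\alpha/2}\,\mathrm{SE}(t)$ with the standard error
from the pooled within-group variance at each $t$; they are not
simultaneous bands. Pairwise category comparisons refit the two
categories' subjects only (rather than contrasting within the full
model) — an explicit assumption, chosen because the permutation
distribution of a two-group comparison is then exact for those groups.
Subjects with missing group labels are dropped from this stage only,
with counts recorded.

# Outcome regression

The later 2-h glucose value is categorized into seven left-closed,
right-open intervals with default cutpoints 3.27, 3.89, 6.39, 6.90,
7.8, 8.84 mmol/l and $[3.89, 6.39)$ as the reference; the half-open
convention places a boundary value (e.g. exactly 7.8, the GDM
threshold) in the upper interval. Five multinomial logistic models
relate the category to early-pregnancy curve features: BMI plus either
the three FPC scores, the fasting value, the 2-h value, the AUC, or the
shape index — one simple measure at a time, since they are collinear.
All covariates enter untransformed and continuous; analysis is
complete-case with dropped counts recorded. Fitting is by maximum
likelihood (`nnet::multinom`), with odds ratios, Wald 95% CIs and
p-values from the estimated Hessian. Comparisons of a covariate's
effect between two outcome categories are Wald contrasts on the joint
covariance — a reconstruction, since published between-category
p-values of this kind rarely state their test. Coefficients exceeding
20 on the per-SD scale trigger a separation warning rather than an
error.

# The synthetic cohort generator

No real OGTT cohort ships with the package; `simulate_ogtt_cohort()`
generates cohorts with the statistical structure the pipeline assumes,
and a ground-truth bundle (`ogtt_truth()`) for recovery tests. Subject
$i$'s true curve is
$$x_i(t) = \mu(t) + \sum_{k=1}^{3} z_{ki}\,\xi_k(t) + s_{b(i)},$$
observed at the five canonical times plus independent
$N(0, \sigma_\epsilon^2)$ noise. Components:

* $\mu(t)$: natural cubic interpolant of the anchors
  (4.0, 5.7, 5.0, 4.5, 4.1) mmol/l — the time-point means of a healthy
  early-pregnancy population, giving the familiar rise-and-fall shape.
* Modes: the normalized constant (level), the centred ramp
  $\propto t - 60$ (early-vs-late contrast, shifting time-to-peak), and
  the one-cycle cosine $\propto \cos(2\pi t/120)$ (oscillation) —
  mutually orthonormal by parity, with modes 2–3 integrating to zero so
  that only the level mode moves the AUC.
* Score SDs (6.0, 1.87, 0.99): calibrated so the three modes' variance
  shares are ≈ 88.1/8.6/2.4% of the signal total; the level-mode SD
  corresponds to a subject-level shift SD of $6.0/\sqrt{120} \approx
  0.55$ mmol/l. These are calibration values, not measured quantities.
* Measurement noise SD 0.15 mmol/l; BMI categories drawn with
  probabilities (0.017, 0.604, 0.281, 0.089) for
  underweight/normal/overweight/obese — these sum to 0.991, and the
  remaining 0.9% of subjects get a *missing* BMI, mirroring the small
  unexplained covariate-missingness typical of cohort reports; additive
  glucose shifts (0, 0, 0.25, 0.55) mmol/l per category emulate the
  clear vertical separation of BMI-group mean curves with similar
  curvature.
* Later outcome: $5.5 + 0.05\,z_1 + 0.10\,z_2 + N(0, 1)$ mmol/l, so the
  top outcome categories are enriched in high-level, late-peak
  subjects.
* Missingness: `round(0.055 n)` subjects lose one randomly chosen time
  point — a deterministic count, so a 1031-subject cohort always has
  exactly 57 incomplete tests.

**What the generator does and does not emulate.** It reproduces the
low-rank-plus-noise covariance structure, the BMI level shifts, the
outcome link, and the incomplete-test fraction. It does *not* emulate
skewness or floor effects of real glucose (values are Gaussian around
the mean curve), physiological constraints (no insulin-glucose
dynamics), within-pregnancy trajectories, or correlated missingness.
Pipeline tests that pass on these cohorts therefore validate the
*statistical machinery* — recovery of known structure, calibration of
tests, determinism — not clinical claims about real populations.

# Known numerical limitations

* **Noise in the smallest components.** With the default noise SD the
  fitted curves retain ~1% of between-curve variance beyond the three
  generating modes, even at the (GCV-selected, near-MISE-optimal)
  smoothing level, so the first three components' cumulative share on
  default synthetic cohorts is typically 98.9–99.1%, and the smallest
  component's score SD is inflated by ~10%.
* **Representation attenuation.** The cosine mode is not in the 5-knot
  cubic spline space; sampling at five points and refitting replaces it
  by its natural-spline interpolant, shrinking its recoverable score SD
  by the interpolant's $L^2$ norm (~0.91). The recovery tests account
  for this factor explicitly.
* **Five points bound the shape rule.** With $J = 5$ at most two peaks
  are expressible; the triphasic pattern uses all four moves, and any
  longer oscillation is unclassifiable by construction.

# Problem sizes used by the test suite

The suite exercises the pipeline at the sizes a desk check can afford:
default cohorts of 1000 subjects for the concentration and correlation
properties; oracle equivalence on 40–50 curves; 200 replicates at
B = 199 for the permutation type-I calibration and 200 replicates for
band coverage; 20–25 replicates of n = 5000 for multinomial recovery.
The full suite runs in about a minute on one CPU.
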