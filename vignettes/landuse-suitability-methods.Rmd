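---
title: "Methods: niche models of landuse, shared suitability, and spatially corrected inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche models of landuse, shared suitability, and spatially corrected inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landsuit)
```

`landsuit` treats forms of human landuse — agriculture, sedentary animal
husbandry, nomadic pastoralism, hunting-and-gathering — the way ecological
niche modelling treats species: each is assumed to have an environmental
envelope in climate and soil, estimable from georeferenced presence records
alone. On top of the fitted suitability surfaces the package builds an index
of shared suitability (ISS) that flags where two landuse forms compete for
the same ground, and a set of regressions — corrected for spatial
autocorrelation — that link suitability to population density, wealth, and
conflict occurrence. Everything can be exercised end-to-end on synthetic
landscapes whose generating parameters are known, so recovery of the truth
is testable.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the limits of what the synthetic experiments can
show.

## The maximum-entropy suitability model

Let the *background* be a uniform sample of cells from the study region
(default 10,000, or all valid cells if fewer), representing available
environment. Given presence records, the model is the Gibbs distribution
over background cells

$$p_i = \frac{\exp(\lambda \cdot f_i)}{Z}, \qquad
  Z = \sum_{j \in \text{background}} \exp(\lambda \cdot f_j),$$

whose weights $\lambda$ minimize the convex objective

$$-\frac{1}{m}\sum_{k=1}^{m} \lambda \cdot f_{(k)} + \log Z
  + \sum_j \beta_j\, |\lambda_j|,$$

the regularized negative mean log-probability of the $m$ presences. This is
the classical presence-only maximum-entropy formulation: the solution is the
maximum-entropy distribution whose feature expectations match the presence
sample, softened by the L1 penalty.

**Feature classes.** Linear and quadratic transforms of each continuous
covariate, rescaled to $[0,1]$ on the background (values outside the
background range are clamped at prediction time), plus one indicator per
observed class of the categorical soil covariate. Quadratic features express
the monotone and unimodal responses this application needs; hinge, product,
and threshold features are deliberately omitted — they buy flexibility at
the cost of testability, and a desk-scale convex problem with two feature
classes can be verified against closed forms.

**Regularization.** The per-feature penalty is
$\beta_j = \beta \cdot \max(s_j, 0.05)/\sqrt{m}$, where $s_j$ is the
presence-sample standard deviation of feature $j$. This is the scaling users
of maximum-entropy niche models expect: the penalty is commensurate with the
sampling error of the feature mean it constrains, and $\beta$ (default 1) is
a single dimensionless multiplier. A flat penalty of order 1 on $[0,1]$
features would dominate the data term — whose gradient is bounded by 1 —
and shrink every weight to exactly zero, so the penalty must scale with
$1/\sqrt{m}$ to be meaningful. The floor 0.05 keeps near-constant features
from escaping regularization entirely.

**Optimization.** Proximal gradient descent (soft-thresholding step) with
backtracking line search; the accepted step grows by a factor 1.3 after each
success, which matters in near-degenerate problems where the local curvature
collapses (for example when all presences share one categorical state and
the optimum runs off to infinity — the iterates then track the path at
geometric speed). Convergence is declared when the objective improves by
less than `tol` (default 1e-8) in one step; non-convergence within
`max_iter` (default 1000) sets a flag and warns rather than failing.
Convexity means restarts agree in objective value to within the tolerance,
which the test suite asserts.

**Output flavors.** `raw` is the Gibbs probability itself, summing to 1 over
the training background (checked to 1e-8 after every fit and prediction).
`cumulative` ranks a cell by the total raw mass at or below its own raw
value — ties inclusive, so equal raw values share one cumulative value — on
a $[0,1]$ scale used for thresholding; the shipped default thresholds (0.18
for agriculture, 0.13 and 0.09 for the animal-keeping forms) only make sense
on this unit scale. `logistic` is $c\,r/(1+c\,r)$ with $c = e^H$ and $H$ the
entropy of the fitted distribution, the conventional prevalence-scaled
"probability of occurrence": a cell of typical (entropy-level) raw value
maps to 0.5.

**Evaluation.** Model quality is the cross-validated AUC: presences are
split into $k = 10$ folds (background shared), and the held-out presences
are ranked against the background by the model's linear predictor; AUC is
the normalized Mann–Whitney statistic with ties counted half. Variable
importance is *permutation* importance — the mean drop in held-out AUC when
a covariate's values (and hence its derived features) are permuted across
evaluation cells, averaged over `n_runs` splits and renormalized to sum
to 1. This deliberately departs from the path-dependent "percent
contribution" of the original maximum-entropy tool, which depends on the
training trajectory of one particular optimizer and is not reproducible
outside it. Whether one prefers 10 folds or 10 replicate runs, both knobs
(`k`, `n_runs`) exist.

## The index of shared suitability

ISS should be near 1 where two landuse forms are *both* well suited, near 0
where one clearly dominates or both are poor. The default formula is

$$\mathrm{ISS}(s_1, s_2) = \max\!\big(0,\ \min(s_1, s_2) - |s_1 - s_2|\big),$$

which provably satisfies all three boundary behaviors, is symmetric, and
maps $[0,1]^2$ into $[0,1]$. The formula is name-selectable
(`compute_iss(..., formula =)`), with a harmonic-mean variant
$2 s_1 s_2/(s_1+s_2)$ and a damped product $s_1 s_2 (1-|s_1-s_2|)$ shipped;
all selectable formulas are run through one shared property suite
(symmetry, range, corner pins) so a different published definition can be
dropped in without touching callers. ISS is computed on logistic-flavor
surfaces by default, since those are the interpretable
probability-of-occurrence maps.

Deviation maps compare a thresholded binary prediction against a reference
binary classification cell by cell, coding agreement (0/1), model-only
presence (2), and reference-only presence (3); the package expects the
reference grid ready-made, since reclassifying an external landuse
taxonomy into these categories is a judgment call no algorithm should hide.

## Spatial statistics

Raster samples are spatially autocorrelated, so ordinary correlation tests
overstate significance. The package implements:

- **Moran's I** (dense weights for point samples; a shift-based lattice
  version for full grids) with the usual null expectation $-1/(n-1)$.
- **Correlograms** over equal-frequency distance classes (default 10;
  classes with fewer than 8 pairs are merged), planar Euclidean distances.
- **The corrected correlation test**: Pearson's $r$ is kept, but the test
  uses an effective sample size. Each variable's spatial covariance matrix
  is estimated piecewise-constant over the distance classes of its
  correlogram; with $B$ the centering projector, the sampling variance of
  $r$ under independence is estimated as
  $\mathrm{tr}(B\Sigma_x B\Sigma_y) / [\mathrm{tr}(B\Sigma_x)\,
  \mathrm{tr}(B\Sigma_y)]$, the effective sample size is one plus its
  reciprocal (capped at $n$, so the adjusted degrees of freedom
  $\mathrm{df}_{adj} = M - 2$ never exceed $n-2$), and
  $F_{adj} = \mathrm{df}_{adj}\, r^2/(1-r^2)$ is referred to
  $F(1, \mathrm{df}_{adj})$. For white noise the correction vanishes
  ($M \to n$); the acceptance suite verifies the empirical type-I error on
  independent-but-autocorrelated field pairs stays near the nominal level
  while the naive t-test's error is grossly inflated — the core correctness
  claim of this module.
- **Moran eigenvector maps**: a binary distance-band connectivity (the
  default truncation is the longest minimum-spanning-tree edge, the
  smallest distance that keeps the graph connected) is double-centered and
  eigendecomposed; eigenvectors with positive eigenvalues, orthogonal to
  each other and to the constant, serve as spatial covariates. Selection is
  greedy forward selection minimizing the absolute Moran's I of regression
  residuals, stopping when residual autocorrelation is no longer
  significant under a permutation test (199 permutations, two-sided,
  alpha 0.05) or `max_k` is reached. The stop rule is this package's
  choice; published applications of eigenvector filtering rarely state one.

## Regressions

Population and wealth responses are modelled on the $\log_{10}(x+1)$ scale
(zeros retained — settlement absence is informative; an exclusion flag
would be the caller's own filter). Two mean models are compared by AIC:

- ordinary least squares (3 parameters including the residual variance);
- a continuous two-segment **breakpoint** model
  $y = a + b\min(x, c) + d\max(x-c, 0)$ — four mean parameters — fitted by
  exhaustive grid search over $c$ (5th–95th percentile of the predictor,
  step 0.005, ties to the smallest $c$; at least 3 points required on each
  side), with the linear subproblem solved exactly at each candidate. Grid
  search is deterministic and immune to the local optima that
  derivative-based knot estimation can fall into at desk scale. AIC uses
  the Gaussian likelihood with the variance counted as a parameter
  ($k = 5$); the convention is stated because published applications often
  leave theirs unstated.

Both models extrapolate to whole-grid prediction surfaces by
back-transforming the fitted mean ($10^{\hat y} - 1$, floored at 0);
residual maps are differences on the natural scale, where the asymmetry of
positive versus negative residuals is an expected artifact of modelling on
the log scale. Conflict occurrence is a binomial GLM (IRLS via `stats::glm`)
of conflict/no-conflict labels on ISS plus selected spatial eigenvectors,
reporting Wald tests, the likelihood-ratio chi-square against the
intercept-only model, and classification accuracy at probability 0.5.

## The synthetic-data generator

The generator exists so that every analysis stage can be tested against a
known truth; its defaults *are* the study conditions of the package's
acceptance experiments.

- **Continuous fields** are Gaussian random fields built by convolving
  white noise with an L2-normalized Gaussian kernel (bandwidth = the
  autocorrelation range, in cells; default ranges 10 and 15 for the two
  climate-like fields). Every cell is exactly standard normal; padding by
  three bandwidths removes edge effects. Kernel convolution was chosen over
  spectral methods because it is exactly reproducible, wrap-free, and fast
  at the 10^4–10^5-cell scale the package targets.
- **Soil** is a categorical field cut from the quantiles of an auxiliary
  random field (default 4 classes, range 8), giving spatially coherent
  patches rather than i.i.d. codes — categorical features deserve testing
  under realistic patchiness.
- **The true niche** is a logistic function of linear and quadratic terms
  plus per-class soil offsets. The default "strong" niche (unimodal in one
  covariate, increasing in the other, graded soil preference, mean
  suitability about 0.2) is strong in the specific sense that the true
  suitability surface itself separates presences from background with AUC
  near 0.9 — an upper bound no fitted model can beat; recovery experiments
  ask the fit to get close to that bound and to rank-correlate with the
  truth.
- **Presences** are drawn without replacement with probability proportional
  to true suitability; default counts per landuse type (290, 150, 100, 47)
  span the sample sizes typical of curated ethnographic/agronomic point
  records.
- **Population** inverts the analysis model: on the $\log_{10}(x+1)$ scale,
  a continuous two-segment function of suitability — defaults
  $(a, b, c, d, \sigma) = (0.2, 6.0, 0.3, 0.5, 0.4)$, i.e. strong
  dependence below a knot at 0.3 and weak dependence above, with Gaussian
  noise — then back-transformed and floored at zero. The GDP generator
  reuses the same machinery with a lower knot (0.1) and steeper lower
  segment, mirroring the qualitative wealth-vs-suitability shape.
- **Conflicts** are uniform random localities labelled by
  $\Pr(\text{conflict}) = \mathrm{logit}^{-1}(\alpha + \beta\,
  \mathrm{ISS})$, defaults $\alpha = -2.5$, $\beta = 5$, 500 localities.

What the generator does **not** emulate: real climate covariance structure
(fields are isotropic and Gaussian), coastlines and nodata geometry,
observation bias in presence records (sampling is exactly proportional to
suitability), and spatially structured *residual* confounding in the
conflict labels (conditional on ISS, labels are independent — so the
eigenvector selection stage typically, and correctly, selects nothing on
synthetic conflict data). Passing recovery tests therefore demonstrates the
correctness of the machinery, not the realism of any particular ecological
claim about real landscapes.

## Reproducibility and numerical choices

Every stochastic function takes an explicit seed and restores the caller's
RNG state. The pipeline derives per-stage seeds by hashing the stage name
into the master seed (`derive_seed`), so adding a stage never perturbs the
streams of existing ones, and a rerun with the same configuration is
bit-identical. Grids are ESRI ASCII with 6-significant-digit output for
non-integer values (integers and the nodata sentinel verbatim); values
already at that precision round-trip exactly. Cell membership follows a
half-open rule (east/south cell wins on shared edges), matching row-major,
north-first storage. Coordinates are treated as planar throughout — the
synthetic world is abstract, and great-circle geometry is out of scope.

Problem sizes used by the test and acceptance experiments — for example a
200 x 200 landscape with 200 presences and a 10,000-cell background for
niche recovery, 1000 replicate field pairs at $n = 200$ for the type-I
calibration, 100 replicates for breakpoint and conflict recovery — were
chosen as the smallest designs at which the statistical claims under test
are comfortably resolvable.

## Known limitations

- One categorical covariate per stack (soil); multiple categorical layers
  would need a small extension of the feature expansion.
- The cumulative transform is defined relative to the training background;
  with a non-exhaustive background it is an estimate of the ideal rank
  transform.
- The corrected correlation test inherits the piecewise-constant covariance
  approximation of its correlogram; with very few distance classes or tiny
  samples the effective sample size is rough (it is clamped to $[3, n]$).
- Unseen soil classes at prediction fall back to the baseline (all
  indicators zero) with a warning — graceful, but predictions there carry
  no soil information.
- The exact functional form of a published shared-suitability index can be
  substituted via the pluggable formula interface; the default here is the
  simplest form satisfying the stated boundary behavior, not a claim of
  equivalence to any specific published equation.
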