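---
title: "Estimating average treatment effects: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating average treatment effects: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmethods)
```

## The estimand and the estimator families

For a binary treatment $A$, binary (or bounded) outcome $Y$ and a sufficient
confounder set $W$, the package targets the average treatment effect
$\psi = E[Y(1)] - E[Y(0)]$ — for a binary outcome, a marginal risk
difference.  Identification rests on the usual assumptions (consistency,
conditional exchangeability given $W$, positivity, non-interference); the
package estimates, it does not adjudicate identification.

Four estimator families are implemented, each a different factorization of
the same estimand:

1. **G-computation** models the outcome mechanism $E(Y \mid A, W)$.  The
   nonparametric route (`np_gformula`) averages stratum-specific arm
   contrasts over the empirical confounder distribution; the saturated
   regression route (`saturated_gformula`) is the identical computation
   through a cell-indicator least-squares fit; the parametric route
   (`parametric_gcomp`) fits arm-specific regressions and averages the
   predicted potential-outcome surfaces.
2. **IPTW** models the treatment mechanism $g(W) = P(A=1 \mid W)$ and
   reweights subjects by the inverse probability of the arm they actually
   occupy (`fit_propensity`, `ht_weights`, `stabilized_weights`,
   `iptw_ate`, `msm_ate`).
3. **Doubly robust** combinations use both nuisances: weighted regression
   adjustment (`iptw_ra`) and the augmented estimating-equation form
   (`aiptw`), consistent when either nuisance model is correct.
4. **TMLE** (`tmle_ate`) starts from any initial outcome fit and moves it
   minimally — a logistic fluctuation along the clever covariates — until
   the efficient score equations are solved, keeping the plug-in means
   inside the parameter space.

On an all-categorical frame with saturated nuisance fits all of these
collapse to the same number; the test suite asserts that equivalence to
1e-10, which doubles as a strong cross-validation of the implementations.

## Numerical and design choices

**Regression kernels.** Logistic fits run through iteratively reweighted
least squares (deviance tolerance 1e-10, 100 iterations) with quasi-likelihood
so fractional responses (bounded outcomes, the TMLE fluctuation) are valid.
Rank-deficient design columns are dropped with a warning and zero
coefficients, so `x %*% beta` is always the linear predictor.  Complete
separation (fitted probabilities within 1e-10 of 0/1 alongside diverging
coefficients) is an error naming the offending column, not a silent
degenerate fit.  Fitted probabilities are clipped to [1e-10, 1 − 1e-10] so
downstream logit transforms stay finite.

**Encoding.** Categorical terms are one-hot with the lowest-sorted level as
reference; this affects coefficient values, never the marginal estimates,
which are averages of predictions.  Saturated specifications expand to
observed-cell indicators without an intercept.  Encoding is deterministic
(term order, then level order) and prediction on an unseen level is an
error.

**Propensity bounding.** Fitted propensities are clipped to [0.01, 0.99] by
default — probabilities too close to 0/1 produce unstable weights — and any
clipping is recorded in the fit object and surfaced as a near-positivity
warning by `aiptw` when more than 5% of subjects are affected.  The bounds
are configurable; the exact-equivalence checks use effectively unbounded
fits, since the identities hold only for unclipped saturated propensities.

**Weight hygiene.** Stabilized weights should average 1; a mean outside
[0.5, 2] attaches a warning.  `trim_truncate` implements both policies
discussed in the weighting literature: truncation winsorizes at the bounds
(percentile, type-7 quantiles, or absolute), trimming drops the subjects and
records the mask, which the weighted estimators honor.

**Balance metrics.** Standardized differences use
$(m_1 - m_0)/\sqrt{(v_1+v_0)/2}$ per encoded confounder column.  The
weighted rows use Hájek means and frequency-weight variances
$\sum w (x - \bar x_w)^2 / \sum w$; the raw rows use unweighted moments.
This convention is documented because weighted-moment formulas differ across
software at the third decimal.  Overlap densities use the Epanechnikov
kernel with Silverman's rule-of-thumb bandwidth on a 512-point common grid,
padded just beyond the fitted range so no kernel mass is cut off (a constant
propensity gets a 0.001 fallback bandwidth), and renormalized so each series
integrates to 1 on the grid — the FFT-based estimator otherwise carries a
~1e-3 discretization mass error.

**AIPTW.** The canonical form augments each arm's g-computation mean with
the inverse-probability-weighted residual of that arm's outcome prediction.
An alternative formulation seen in worked examples multiplies a stabilized
weight into the pooled-model residual for both arms; that variant is
available behind `variant = "stabilized"` for code-level comparison and is
documented as non-canonical.

**TMLE.** Two separate fluctuation coefficients (one per arm) are used, and
the update divides each epsilon by $g$ or $1-g$, matching the clever
covariates $A/g$ and $(1-A)/(1-g)$.  Initial Q predictions are clipped to
[0.005, 0.995] before the logit transform.  The fluctuation offset is the
observed-arm initial prediction, so the fitted epsilons solve exactly the
two reported score equations; after an IRLS start a Newton polish drives
each |score| below 1e-8 (the deviance-based stop alone can fall short when
clever covariates are large under near-positivity), and when the initial fit
already solves the scores the update is skipped — epsilon is exactly zero,
which is also what makes the saturated-nuisance equivalence exact.  A
continuous outcome is affinely rescaled to [0, 1] before targeting (known
bounds [0, 1] by default, per the frame contract) and the effect mapped
back.  Bootstrapping TMLE is refused at the interface level: resampling
inference for data-adaptive plug-ins lacks theoretical support, and the
influence-function Wald interval is reported instead.

**Super learner.** The ensemble minimizes 5-fold cross-validated negative
Bernoulli log-likelihood over the probability simplex by projected gradient
(500 iterations, tolerance 1e-9) across three GLM learners: main effects,
main effects plus squares of continuous columns and all pairwise products,
and backward-AIC stepwise selection from that augmented design (deterministic
elimination order).  Failed learners are dropped with a warning and weights
renormalized.  The default TMLE nuisances remain plain GLMs; the ensemble is
opt-in, keeping the core dependency-light.

**Bootstrap.** Resampling is seeded and deterministic; percentile intervals
use type-7 quantiles (documented: other software's percentile rules differ
in edge cases); the bias-corrected interval shifts the quantiles by
$z_0 = \Phi^{-1}(\text{fraction of replicates below the estimate})$, with
jackknife acceleration available behind a flag.  More than 10% failed
replicates aborts with advice rather than silently reporting a biased
interval.  B defaults to 1000.

## What the synthetic generators emulate

`generate_sim_cohort` draws a cancer-epidemiology cohort: deprivation
quintile $w_1$, age indicator $w_2$, stage $w_3$, comorbidity $w_4$, a
treatment mechanism with a strong $w_2 w_4$ interaction that forces
near-positivity violations, and potential outcomes stored as event
*probabilities* — the simulated outcome is continuous in (0, 1) and exactly
satisfies the consistency identity $Y = A Y_1 + (1-A) Y_0$.  Storing
probabilities rather than Bernoulli draws removes outcome noise from the
Monte Carlo comparisons, isolating confounding and misspecification bias.
Rounding in the confounder construction is half-away-from-zero; ties have
probability zero under the uniforms, but fixing the convention makes the
stratum distributions unambiguous (`true_sim_ate` enumerates them exactly —
rounding-interval lengths for each stratum given $(w_1, w_2)$ — giving a
sampling-free truth of 0.16737 used by every benchmark).

Because its outcome is deterministic given $(A, W)$, this generator is
deliberately idealized: real cohorts have outcome-level noise, unmeasured
confounding and missing data, none of which these tests exercise.  The
RHC-like generator (`generate_rhc_like`) is the complementary fixture — a
synthetic critical-care cohort with a binary mortality outcome drawn from a
logistic mechanism over five mixed-type confounders, with the generating
coefficients stored so the implied truth is recoverable by large-sample
standardization (`rhc_like_truth`).  It emulates the *shape* of the classic
right-heart-catheterization teaching cohort (variable names, types, mild
confounding), not its empirical distributions.

In the Monte Carlo harness (`run_monte_carlo`) the "misspecified"
specifications are main-effects factor models omitting the $w_2 w_4$
interaction, with a linear outcome family for the regression-based
estimators (the conventional default for a continuous outcome); the
"correct" specifications add the interaction with a logistic outcome family,
under which both mechanisms are exactly representable.  Per-replicate seeds
derive from one master seed, so every experiment is reproducible.

## Problem sizes used by the checks

The equivalence suite runs on the 8-row worked example and 50 random
discrete frames of ~120 subjects; TMLE internal consistency on 100 frames
including positivity-stressed ones; double-robustness recovery on 200
replicates of n = 2000 per misspecification leg; the misspecification
ordering on 500 replicates of n = 1000; bootstrap coverage on 500 simulated
two-arm cohorts of n = 200 with B = 400.  These sizes give Monte Carlo
standard errors small enough for 3-sigma bias checks and coverage bands of
[0.92, 0.98] while keeping the suite comfortably runnable on one CPU.

## Known limitations

Single time-point binary treatments only: no time-varying regimes, no
multi-valued or continuous treatments, no ATT estimand, no matching, and no
cross-fitting (the natural next step for data-adaptive nuisances).  The
bootstrap, not the delta method, is the supported variance route for the
non-data-adaptive estimators; model-based standard errors from the component
regressions are never reported, since they ignore the multi-step estimation.
Survey designs, clustering and missing-data imputation are out of scope —
frames with missing values are rejected at construction.
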