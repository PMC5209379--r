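---
title: "Stable feature selection for functional connectivity classifiers: methods and design"
author: "ConnStab package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable feature selection for functional connectivity classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state fMRI yields, per subject, one mean signal time series for
each of R regions of interest (ROIs); with R = 84 this gives
R(R-1)/2 = 3486 pairwise Pearson correlations, Fisher-z transformed into a
feature vector. These features are strongly collinear — region pairs
within the same functional network carry nearly redundant information —
and the number of features dwarfs typical case-control sample sizes. Under
these conditions classical stepwise logistic regression is known to select
features almost arbitrarily among collinear candidates, while
elastic-net-penalized regression tends to shrink correlated features
toward each other and select them as a group. ConnStab implements both
classifiers and the resampling machinery to compare them on two axes:
held-out discrimination accuracy (AUC) and consistency of feature
selection across resampling iterations.

## Featurization

Per subject the pipeline is: nuisance regression → band-pass filter →
Pearson correlation matrix → Fisher z → canonical pair vectorization.

**Nuisance regression** (`nuisanceRegress`) replaces each ROI signal by
its OLS residual on an intercept plus supplied regressors. In synthetic
mode the default regressors are a linear trend and the mean across ROIs
(standing in for the global signal); motion and tissue-compartment
regressors are used when supplied. Rank-deficient regressor sets are
pruned with a warning.

**Band-pass filtering** (`bandpassFilter`, default 0.01–0.1 Hz) is an
ideal discrete-Fourier mask: coefficients with frequency magnitude outside
the band are zeroed (the DC term always), and the series is
inverse-transformed. Realized this way the filter is an exact orthogonal
projector, which buys two testable identities: applying it twice equals
applying it once, and the output variance equals the sum of retained
periodogram ordinates (Parseval). A design alternative — folding linear
detrending into the filter — destroys both identities, because the
band-limited output generally has a nonzero trend projection; detrending
therefore lives in the nuisance-regression step (on by default in
`buildFeatureDataset`), keeping each operator exact.

**Fisher z** is `0.5 * log((1 + r) / (1 - r))` with r clipped to
±(1 − 1e-7) so that degenerate correlations (identical columns in
synthetic edge cases) stay finite.

**Pair ordering.** Features are indexed by the strict upper triangle in
row-major order: (1,2), (1,3), …, (1,R), (2,3), …. No convention is
canonical in the field, but cross-run feature identity requires fixing
one; the package uses this ordering everywhere (`pairIndexTable`).

The assembled dataset is a `SummarizedExperiment` subclass
(`ConnectivityDataset`): assay `z` is pairs × subjects, `rowData` holds
the pair index, `colData` the subject manifest (diagnosis, site,
demographics).

## The two classifiers

**Elastic net** (`fitElasticNet`) minimizes

$$-\frac{1}{N}\sum_i\left[y_i\eta_i - \log(1+e^{\eta_i})\right]
  + \lambda\sum_j p_j\left[\tfrac{1-\alpha}{2}\beta_j^2
  + \alpha|\beta_j|\right]$$

with an unpenalized intercept, on internally standardized predictors
(mean 0, 1/N-variance 1), coefficients reported on the original scale.
The solver is cyclic coordinate descent on the penalized weighted
least-squares subproblem inside IRLS (proximal Newton), with warm starts
along a descending lambda path and active-set iteration — the standard
architecture for this model family. Convergence is declared when the
maximum weighted squared coefficient change falls below `tol` (default
1e-7), the convention of the widely used coordinate-descent
implementations; solutions are verified in the test suite by subgradient
stationarity (KKT residual ≤ 1e-4) and against independent oracles
(dense objective grids, proximal gradient, a quasi-Newton minimizer, and
a reference implementation). λ_max — the smallest lambda with an all-null
penalized solution — is computed from the score at the null model; when
forced covariates (penalty factor 0) are present the null model includes
them, so λ_max uses residuals from the forced-covariates-only fit rather
than y − ȳ (otherwise the all-null property at λ ≥ λ_max would fail).
α defaults to 0.5 (a full mixture of ridge and lasso); `alphaSweep`
produces deviance-vs-λ curves over an α grid for choosing it.

**Lambda selection** (`cvSelectLambda`) follows the
mean-of-per-repeat-minimizers rule: per repeat, stratified folds are
drawn, out-of-fold binomial deviance is accumulated along the λ path, and
the deviance-minimizing λ recorded; the selected λ is the mean of the
per-repeat minimizers. The published design this reproduces states
"100-fold cross-validation" with 100 iteratively determined λ values,
which is ambiguous between 100 folds and 100 repeats; the package
defaults to repeats × folds = 100 × 10 and exposes `cvFolds = 100,
cvRepeats = 1` as the literal variant. Fold fits use a looser working
tolerance and a bounded IRLS budget (`solverTol = 1e-6`,
`solverMaxit = 15`) plus the usual deviance-saturation early exit: fold
fits only rank lambdas, and separable training folds at tiny λ would
otherwise burn arbitrary effort refining coefficients that do not change
the ranking. Final fits at the chosen λ always use the strict settings.

**Stepwise logistic regression** (`fitStepwise`) is the bidirectional
AIC-greedy search: starting from the full candidate model, every
single-term drop and add is scored by AIC = −2ℓ + 2(1 + k); the best
strictly improving move is taken; the search stops at a local minimum.
Starting from the full model matches the common convention of the
classical stepwise tools when given a full formula; the empty-start
(`direction = "forward"`) and drop-only variants are options. Tie-breaks
are deterministic: drops before adds, then lowest column index.
Likelihood fits use IRLS with step-halving and a 1e-8 ridge stabilizer,
so quasi-separated candidate models stay finite; non-converged fits keep
their last iterate and still yield an AIC, mirroring how the classical
tools behave in practice.

**VIF** (`computeVif`) is 1/(1 − R²) of each column regressed on the
rest; values above 5 are read as serious multicollinearity, and the
median VIF across stepwise models is recorded per iteration.

## Subsample validation

`runStability` draws `nIterations` stratified 2/3 training subsamples
without replacement (test = remaining 1/3; stratification keeps both
classes in both parts, an unstratified mode exists). Per iteration,
training rows only are used to: prefilter candidate pairs by
point-biserial |r| > 0.35 against diagnosis; select λ by repeated CV; fit
both models. The held-out third is scored by rank-based (Mann–Whitney)
AUC with midrank ties. "Selected" means a nonzero coefficient at the
chosen λ for the elastic net, and a retained term for the stepwise model.
Aggregation yields per-pair selection frequencies, consensus networks
(frequency ≥ 50% by default), AUC means with empirical 2.5/97.5
percentile intervals, and median model sizes.

Center (scanner) covariates: `addCenterCovariates` builds treatment-coded
site dummies (reference = first site in sort order). They are exempt from
the prefilter and forced into both models — penalty factor 0 for the
elastic net, non-droppable for stepwise — since they are adjustment
covariates, not candidates.

An iteration whose model fitting fails is recorded as skipped (missing
AUC, excluded from frequency denominators); the run aborts if more than
10% of iterations skip. The whole run is a pure function of (dataset,
config, seed): one master seed yields, up front, an order-independent
vector of per-iteration sub-seeds, so iterations are reproducible
regardless of execution order.

## The synthetic cohort generator

`simulateCohort` emulates the structure of a four-site case-control
resting-state study: 53 AD and 118 control subjects, 84 ROIs, per-site
usable volume counts 194/114/174/114 and sampling intervals
2.61/3/2.58/3 s, demographics drawn to match the published group summaries
(sex ratio 31/53 vs 61/118; age 72.4 (8.8) vs 70.4 (6.2); education
11.4 (2.1) vs 13.6 (3.1); MMSE 22.5 (4.4) vs 28.8 (1.0)).

The control correlation matrix is block structured — 12 blocks of 7 ROIs
with within-block correlation 0.5 and between-block 0.1 — because the
real features group by functional network, and block structure is the
simplest mechanism that reproduces the collinearity the study design
hinges on. The AD matrix subtracts 0.25 from 20 randomly chosen
within-block pairs; drawing affected pairs within blocks makes the
affected features themselves collinear, reproducing the condition under
which stepwise selection becomes arbitrary. Both matrices are repaired to
positive definiteness by eigenvalue clipping at 1e-4 and rescaling to
unit diagonal — the simplest repair with bounded distortion — and the
generator refuses configurations where repair moves any target entry by
more than 0.05. Subjects are stationary Gaussian AR(1) processes
(φ = 0.3) whose innovation covariance is the group matrix times a
per-site variance multiplier exp(N(0, 0.1²)). Site effects are variance
multipliers only: correlation features are scale invariant, so this
perturbs estimation noise without moving feature means, which matches the
intent of testing robustness rather than planting a site confound. One
site in the emulated study used an eyes-open protocol; no quantitative
effect size is available for that difference, so it is not modeled.

What the generator does **not** emulate: subject-level heterogeneity of
the true correlation structure (every subject in a group shares one
target matrix, so between-subject feature variance is purely estimation
noise), head motion, hemodynamics, spatial structure, or non-Gaussian
artifacts. Consequently the planted effects are easier to detect than
AD effects in real data — synthetic AUCs run near ceiling rather than at
the 0.7–0.8 of clinical multicenter data — and passing recovery tests
demonstrates correctness of the machinery, not clinical effect sizes.

## Numerical choices and edge cases

- Fisher-z clip at ±(1 − 1e-7); correlation of a zero-variance ROI is an
  error naming the ROI.
- Positive-definite repair floor 1e-4; distortion ceiling 0.05.
- Elastic-net coordinate updates carry a ~1e-12 absolute guard on the
  soft threshold so that λ = λ_max lands exactly on the null model
  instead of being tipped by accumulation rounding.
- An empty prefilter set is legal: both models fall back to the
  intercept-only classifier and the held-out AUC is 0.5 by construction.
- `summarizeAuc` refuses fewer than 40 completed iterations by default
  (percentile stability); internal aggregation of small diagnostic runs
  relaxes this.
- The noise/signal behavior of `cvSelectLambda` is checked against both
  the heavily regularized upper half of the grid (noise) and the
  grid midpoint plus a paired noise-vs-signal comparison (signal); on a
  four-decade logarithmic grid the geometric midpoint is so small that
  only the paired comparison is informative, so both are asserted.

## Problem sizes used by the test suite

Unit tests run on reduced shapes chosen to keep the suite fast while
exercising every code path: 16-ROI/36-subject cohorts for pipeline
round-trips, 100 subsample iterations with 10 × 10-fold CV for the
qualitative elastic-net-vs-stepwise comparison (5 independent cohort
seeds), 200 iterations for the duplicated-feature contrast and the
center-covariate robustness check, and 20 seeds for distributional
properties. The full published design (1000 iterations, 100 CV repeats)
is available by configuration: `stabilityConfig(nIterations = 1000,
cvRepeats = 100)`.

## Known limitations

- The elastic-net solver targets the binomial single-response case only.
- Stepwise search cost grows with the candidate set; it is intended for
  use behind the |r| prefilter (dozens of candidates), as in the design
  it reproduces.
- Consensus comparison across runs assumes a shared pair index; datasets
  must be built with the same ROI ordering.
- P-values in the demographics table are asymptotic, matching the tests
  they reproduce; exact small-sample variants are out of scope.
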