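---
title: "Functional random forests for dose-response curves: models, costs, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional random forests for dose-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funrf)
```

## The problem

Pharmacogenomic screens measure the response of a sample (typically a
cancer cell line) to a compound at an ordered series of concentrations,
producing a *dose-response curve* per sample-drug pair. Predictive models
in this field usually collapse that curve to one scalar — AUC, IC50, EC50
or Amax — and regress the scalar on genomic features. The scalar hides
clinically relevant structure: two curves can share an AUC yet differ
completely in their behavior at high doses, which is exactly the region
that matters when choosing a dose.

`funrf` implements random-forest regression whose trees treat the whole
curve as the response. Two changes to the classical algorithm accomplish
this:

1. **Node costs are functional.** Instead of the sum of squared deviances
   (SSD) of one scalar, the deviance of a node is accumulated region-wise
   over the curve, or — when per-dose replicate distributions are
   available — as an f-divergence between each sample's per-dose response
   distribution and the node's mixture distribution.
2. **Leaves store curves.** A leaf keeps its member samples' full response
   curves. To predict, the forest-weighted training responses at each dose
   are summarized by a Gaussian; the mode of that Gaussian (its mean) is
   the predicted response at that dose, and its SD gives an uncertainty
   band. Repeating over doses yields the predicted curve.

## Models and node costs

Let $x(i) \in \mathbb{R}^M$ be the features of sample $i$ and $y_j(i)$ its
response at dose $d_j$, $j = 1,\dots,q$. At any node $\eta_P$ a split on
feature $j_s$ at threshold $z$ sends samples with $x(i,j_s) \le z$ left.
The split chosen maximizes the cost reduction
$C = D(\eta_P) - D(\eta_L) - D(\eta_R)$ over all candidate features and
thresholds. The available node deviances $D$ are:

* `ssd` — $\sum_i (y(i) - \bar y)^2$ on a scalar target (the classical
  regression tree, mode `"rf"`).
* `region_ssd` — $\sum_j \sum_i (y_j(i) - \bar y_j)^2$: the curve is
  discretized into regions (by default one per dose) and the per-region
  SSDs are summed (mode `"frf"`; the default).
* `pca` — SSD of the scores on the top principal components of the root
  training response matrix. The basis is fixed at the forest root: scores
  recomputed per node would not be comparable between a parent and its
  children.
* `basis` — the B-spline coefficient deviance
  $\sum_i (c(i)-\bar c)^\top \Phi\, (c(i)-\bar c)$ with $\Phi$ the Gram
  matrix of basis inner products, i.e. the $L_2$ deviance of the
  represented functions.
* `mahalanobis` — $\sum_i (y(i)-\bar y)^\top \Sigma^{-1} (y(i)-\bar y)$,
  the multivariate random forest (mode `"mrf"`). $\Sigma$ is estimated
  once per tree from that tree's bootstrap responses (per-node estimation
  is ill-posed at small leaves) with a ridge of
  $\varepsilon \cdot \mathrm{tr}(\Sigma)/m$, $\varepsilon = 10^{-6}$, or
  supplied as a fixed matrix.
* `kl`, `hellinger` — per dose, every sample's Gaussian
  $\mathcal N(\mu_{ij}, \sigma_{ij}^2)$ (mean and SD over technical
  replicates) is discretized on a shared support grid $\Omega$ and
  compared to the node's equal-weight mixture $\hat\Phi$ by
  $\sum_\Omega \Phi_i \ln(\Phi_i/\hat\Phi)$ (Kullback-Leibler) or
  $\sum_\Omega (\sqrt{\Phi_i}-\sqrt{\hat\Phi})^2$ (squared Hellinger);
  regional costs are summed.

All quadratic costs reduce internally to the SSD of a linearly transformed
response matrix (whitening for Mahalanobis, projection for PCA, a Cholesky
factor of the Gram matrix for the basis cost). That reduction is what makes
the exhaustive split search fast: for a sorted feature the reward at every
threshold follows from prefix sums in $O(nd)$ per feature, implemented in
compiled code as the field's forest packages do. The same reduction
guarantees the textbook identities that the test suite asserts exactly:
region-wise SSD equals Mahalanobis with identity covariance, a functional
forest on a single dose equals the univariate forest under shared seeds,
and the per-dose Gaussian-mode prediction equals the dose-wise weighted
mean of training curves.

The hybrid mode `"frfl"` uses the functional node cost for splitting but
stores a scalar summary metric (AUC by default) in the leaves; it isolates
how much of the functional forest's advantage comes from splitting versus
from curve-valued leaves.

### Prediction weights

A tree assigns a query $x$ the weight $w_i(x,\Theta)$ = (multiplicity of
training sample $i$ in the leaf containing $x$) / (leaf size), counted on
the bootstrap sample; forest weights are the average over trees and sum to
one. Scalar predictions are $\hat y(x) = \sum_i w_i(x) y(i)$; curve
predictions apply the same weights dose-wise, with
$\sigma_j^2(x) = \sum_i w_i(x)\,(y_j(i) - \hat y_j(x))^2$ (the weighted,
$1/n$-style variance — the prediction itself is insensitive to the
estimator choice) reported for uncertainty bands.

### Splitting rules and determinism

Threshold candidates are midpoints between consecutive distinct feature
values, which keeps routing robust to floating-point noise. A fresh
uniform feature subset of size `mtry` is drawn at every node. Splits with
non-positive reward are rejected — this prevents infinite recursion on
constant targets; for the divergence costs, whose reward is not guaranteed
nonnegative by a variance decomposition, the same positivity rule is
applied. Ties are broken toward the lowest feature index and lowest
threshold, so a fit is a deterministic function of (data, hyperparameters,
seed). A node with at most `min_node` samples, or a node where no
candidate feature varies, becomes a leaf.

Default hyperparameters are 150 trees, `mtry = 10` and `min_node = 10`,
the standard configuration for screens of this size.

## Curve fitting and summary metrics

All fitting and integration happens on the log10-dose axis — the scale on
which dilution series are designed and plotted; the linear axis would let
the top decade dominate every integral. Consequences:

* **AUC** is the trapezoidal area between a reference level (1 =
  untreated viability, or a vehicle-control expression level) and the
  curve, normalized by the log-dose width so values are comparable across
  grids. Portions of a curve above the reference are clamped to zero
  contribution by default, following the vehicle-control convention.
* **IC50** is the smallest in-span dose where the fitted curve crosses
  half the reference. Metrics whose defining crossing does not occur
  within the dose span are reported as `NA` ("not reached") — never
  extrapolated, since extrapolated IC values in public databases are
  known to be unstable.
* **EC50 / Amax** come from a four-parameter logistic fit
  $y(d) = A_0 + (A_{\max}-A_0)/(1 + (IC_{50}/d)^\theta)$ by bounded
  Levenberg-Marquardt least squares: $A_0, A_{\max}$ within the data
  mean $\pm\,1.5\times$ range, $\theta \in (0, 10]$, $IC_{50}$ within one
  decade beyond the dose range, multistarted from $\theta_0 \in
  \{0.5, 2, 5\}$ and keeping the lowest deviance. If no start converges
  and `sigmoid_fallback = TRUE`, AUC and IC50 fall back to an
  interpolating B-spline and EC50/Amax are not reached.
* **IC percentiles** of expression curves (`ic_from_polynomial`) fit a
  cubic polynomial in log10-dose and locate the smallest dose where the
  fitted curve has traversed $p\%$ of its total fitted change, counted
  from the trend's starting extremum (from the maximum for decreasing
  curves, from the minimum for increasing ones). This orientation makes
  IC25 $\le$ IC50 $\le$ IC75 in dose order for any monotone trend, and
  still yields IC values for rising curves. Flat fitted curves return all
  percentiles as not reached.

B-splines use equally spaced interior knots over the log-dose span with
repeated boundary knots; with as many basis functions as dose points the
fit interpolates. The Gram matrix is evaluated by trapezoidal quadrature
on a 401-point grid, which is far below the fitting error of interest.

## Function-to-function regression

When expression is measured *after* treatment at several doses, each
predictor is itself a curve. `extract_curve_features()` converts each
sample x protein dose-expression curve into the scalar features used as
model inputs: the control-referenced AUC and the IC25/IC50/IC75 doses of
the cubic fit (a 21-protein panel yields a 21 x 4 feature block per
sample). Two rank-based alternatives are provided: ranking curves by their
least-squares slope against log-dose, and by pairwise dominance (curve A
beats curve B when strictly more than half of A's dose points exceed B's;
curves are ordered by the number of curves beating them). Both rankings
break ties stably — by input order for slopes, and by mean value then
input order for dominance — so they are deterministic.

## The synthetic benchmark

`simulate_drc_cohort()` generates the study conditions every quantitative
check in this package runs under:

* 5 clusters x 15 samples; 10 relevant features (cluster $c$ draws
  feature values from $\mathcal N(c\Delta, \Delta/4)$, so adjacent
  clusters overlap by about 4.6% of their mass — "limited overlap") and
  10 standard-Gaussian noise features, columns shuffled with the mask
  recorded.
* Responses from the four-parameter logistic on 101 log-spaced doses from
  0.0025 to 8 µM, with $A_0 = 1$, $A_{\max} = 0$, $\theta = 2$ fixed and
  per-sample $IC_{50}$ = cluster center (log-spaced 0.01-4 µM)
  $\times\,(1 + U(-0.1, 0.1))$.
* Optional additive Gaussian noise with SD = `noise_level` x the clean
  response range, which pins down what "5% additive noise" means.

The generator's defaults reproduce the 75 x 20 design matrix and 75 x 101
target matrix of the benchmark design. Parameters not fixed by that
design (the logistic constants, cluster centers, jitter width, overlap)
were chosen once as values a screen of this kind would produce and are
exposed as arguments, so benchmark reproduction is tolerance-based rather
than exact.

What the generator does *not* emulate: genome-scale feature
dimensionality (real screens have $\sim 10^4$ features with correlation
structure), heteroscedastic measurement error, non-sigmoid response
shapes, and missing doses. Passing benchmarks on this cohort therefore
demonstrates correctness of the machinery and the qualitative advantage
of functional splitting under the stated noise model, not performance on
any particular real screen.

### Evaluation design

`run_noise_benchmark()` cross-validates a functional forest and a
per-dose baseline — one univariate forest per dose column, since a
univariate forest cannot emit a curve — over a grid of noise levels, tree
counts and fold counts. Models are trained on the noisy targets and
scored by NMAE (mean absolute error / true response range) **against the
noiseless ground-truth curves**. Scoring against the noisy observations
would floor both models at the irreducible noise level
($\approx 0.8\,\sigma$ of mean absolute noise) and erase the comparison;
evaluating against the truth the generator knows is exactly the
advantage a synthetic benchmark offers. `cross_validate()` itself scores
against whatever targets the caller supplies (`truth =`), defaulting to
the observed responses.

One behavior of this generator worth knowing: with *no* added noise, the
per-dose baseline matches the functional forest. Clean targets give every
dose column the full cluster signal, so there is nothing for cross-dose
pooling to recover, and both models sit at the same small leaf-mixing
bias floor set by the IC50 jitter. The functional forest's advantage
appears as noise is added — single-dose split searches degrade while the
region-wise cost, which pools evidence across all doses, does not — and
grows with the noise level.

`bootstrap_compare()` refits both models on bootstrap resamples and
evaluates on the out-of-resample samples. Within a replicate the two
models consume an identical RNG stream, so the comparison is paired and
two identical configurations tie exactly; the output is the distribution
of MAE differences.

Problem sizes used by the shipped checks — 75-sample cohorts, 5-fold CV,
50-150 trees, 5 repeats, 50 bootstrap replicates — were chosen so the
full battery runs in minutes on one core while keeping the Monte Carlo
spread of each comparison well inside the margins being asserted.

## Numerical choices

* Divergence support grid $\Omega$: 256 equally spaced points spanning
  the pooled response means $\pm\,4\times$ the largest SD, recomputed at
  each tree root and fixed down the tree so parent and child costs are
  comparable. Probability masses are floored at $10^{-12}$ before logs;
  SDs are floored at $10^{-6}$ to avoid point masses.
* Replicate SDs absent: the divergence costs degrade gracefully to
  near-point masses at the observed values via the SD floor.
* Zero-reward and numerically-zero-reward splits (reward
  $\le 10^{-12} \times$ parent deviance) are rejected.
* The interpolating-spline, closed-form-divergence and split-oracle
  checks in the test suite run at $10^{-8}$, $10^{-3}$ and exact-match
  tolerances respectively; stochastic benchmark assertions use margins
  wide enough that a different seed does not flip them.

## Known limitations

* The divergence-cost split search is quadratic in node size per feature
  and evaluates densities on the full grid; it is intended for cohorts of
  hundreds of samples, not tens of thousands.
* No out-of-bag error machinery: evaluation is by cross-validation and
  bootstrap comparison.
* No surrogate splits or missing-feature handling — routing a query with
  a missing value on a split feature is an error.
* Variable importance is the frequency measure (selected / picked, counted
  once per node); permutation importance is out of scope. A feature's
  "picked" count includes nodes where no admissible split existed, so
  importances on very small cohorts are conservative.
* Only the two named divergences (KL, squared Hellinger) are provided,
  and only the four-parameter logistic (no five-parameter or
  re-parameterized Hill variants).

## A worked example

```{r example, eval = FALSE}
co <- simulate_drc_cohort(noise_level = 0.10, seed = 42)
fit <- frf(co$features, co$responses, trees = 150, seed = 1)
pred <- predict(fit, co$features[1:5, ])    # long tibble with .pred, .pred_sd
autoplot(pred)

cv_f <- cross_validate(co$features, co$responses, model = "frf",
                       folds = 5, seed = 7, truth = co$clean, trees = 50)
cv_r <- cross_validate(co$features, co$responses, model = "rf_per_dose",
                       folds = 5, seed = 7, truth = co$clean, trees = 50)
c(frf = cv_f$nmae, rf = cv_r$nmae)
```
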