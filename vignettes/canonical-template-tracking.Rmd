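---
title: "Canonical template tracking: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical template tracking: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cttrack)
```

## The procedure

Canonical template tracking asks whether, and how strongly, a *specific*
neural representation is active during a task. The procedure has four
stages, each backed by a module of this package:

1. **Extraction** turns raw recordings into labeled observations x units
   activity patterns (`pattern_set`): run-wise or trial-wise least-squares
   fits (`fit_run_glm()`, one regressor per condition or per trial),
   univariate or multivariate noise normalization (`noise_normalize()`),
   supertrial averaging (`make_supertrials()`), temporal smoothing
   (`smooth_temporal()`), and principal-component reduction
   (`reduce_dimensions()`).
2. **Template estimation** averages the localizer patterns of each
   condition into one canonical template per condition
   (`estimate_templates()`), optionally restricted to an ROI
   (`select_roi()`) or a time window (`select_time_window()`).
3. **Tracking** computes, per main-task observation and template, an
   activation index (`similarity_index()`, `crossvalidated_index()`,
   `regression_partition()`, `classifier_tracking()`), and reduces it to
   the interpretable quantity: the **relative activation index**
   (`relative_activation()`), target minus baseline template, oriented so
   positive always means "target more active". `run_searchlight()` and
   `run_temporal()` repeat the computation over sphere centers and time
   bins.
4. **Inference** tests relative indexes at the group level with
   nonparametric tools (`wilcoxon_signed_rank()`, `permutation_test()`,
   `cluster_correct()`, `fdr_correct()`).

The model behind the simulator — and implicitly behind the estimators — is
additive: a main-task trial is a weighted sum of the condition templates
plus stationary Gaussian noise,
$y = \sum_k w_k t_k + \varepsilon$, $\varepsilon \sim N(0, \Sigma)$ with
$\Sigma = \sigma^2\,[(1-\rho) I + \rho S]$ and $S$ a squared-exponential
spatial kernel (length-scale 2 units). Templates are constructed with an
exactly controlled population correlation by mixing i.i.d. Gaussian rows
through the Cholesky factor of the target $K \times K$ correlation matrix,
then standardizing each row (which leaves Pearson correlations untouched).

## Why relative indexes

An absolute correlation or distance between a template and task data mixes
content-specific reactivation with everything the two measurements share:
global activation level, baseline shifts between sessions, general task
engagement. Subtracting a baseline template's index from the target
template's index cancels these shared components; the package therefore
treats the relative index as the primary outcome, and the mapping drivers
reduce each sphere/bin to the mean relative index over target-condition
observations. Pearson values are Fisher-z transformed *before*
subtraction or averaging (variance stabilization; the difference of z
values is also what the paired tests consume). An absolute "own-condition"
tracker (`tracker_config()` without target/baseline) exists for
diagnostics — it is symmetric in its two inputs, which the relative
contrast deliberately is not — but is not baseline-controlled and should
not be used for inference.

## The noise bias and cross-validated distances

Naive distances between noisy patterns are biased away from zero: for two
independent measurements of the *same* pattern,
$E\|y_c - y_{c'}\|^2 = 2\sum_v \mathrm{Var}_v$ — pure noise reads as
dissimilarity, and the statistic has no meaningful zero. The
cross-validated estimator
$\widehat{d^2} = \mathrm{mean}_{c \ne c'} (t - \bar y_c)'(t - \bar y_{c'})$
keeps the template fixed and multiplies *independent* difference vectors,
so the noise terms cancel in expectation and zero means "pattern equals
template". `bias_audit()` demonstrates both facts by simulation and
reports the analytic expectations alongside; the acceptance suite requires
the naive mean to match $2\sum_v \mathrm{Var}_v$ within 10% and the cv
mean to sit within 2 standard errors of zero (V = 200, sigma = 0.5,
20 chunks, 1000 repetitions).

Two caveats are deliberate. First, when the template itself is estimated
from noisy localizer data, its own noise is *shared* across all chunk
pairs and contributes a residual positive bias of
$\mathrm{Var}(\hat t)$ to the cv estimator; the package documents this
rather than correcting it, because no agreed correction exists for the
fixed-template scheme. Second, negative cv and Mahalanobis values are
genuine outcomes of an unbiased estimator near zero; they are reported
(flagged with `may_be_negative`), never clipped, since clipping would bias
group statistics upward.

The "cross-validated correlation" has no canonical formula in the
literature; this package uses a reliability-adjusted form — the mean
covariance between template and chunk means, normalized by
$\sqrt{\mathrm{var}(t) \cdot \mathrm{mean}_{c\ne c'}\mathrm{cov}(\bar y_c, \bar y_{c'})}$ —
one admissible reading in which the cross-chunk covariance replaces the
noise-inflated within-chunk variance in the denominator. When the
cross-chunk covariance is non-positive (noise-dominated data) the index is
undefined and returned as `NA` with a warning.

## Variance partitioning and classifiers

When several templates compete, independent similarity values double-count
their shared variance. `regression_partition()` regresses each
unit-centered pattern on all unit-centered templates at once, returning
betas, the full-model R², and signed semi-partial correlations
$sr_k = \mathrm{sign}(\beta_k)\sqrt{R^2_{full} - R^2_{-k}}$ (each
template's unique contribution; verified against the residualization
definition to 1e-10). Centering across units removes the global-mean
component — the univariate signal that can reflect general task
processing — and no intercept is fitted thereafter. Collinear templates
are refused with the design's condition number rather than silently
producing unstable betas.

`classifier_tracking()` trains a linear discriminant on localizer
exemplars with a pooled within-class covariance shrunk toward its diagonal
(intensity 0.1 by default; 0 requires a nonsingular covariance). Beyond
accuracy, it reports per-template signed distances to each one-vs-rest
hyperplane, scaled to pattern units — the trial-wise confidence analog of
the similarity indexes. Ties in the multi-class argmax resolve to the
lowest condition index, deterministically.

## Mapping over space and time

`run_searchlight()` iterates a voxel sphere (`sphere_offsets()`, all
integer offsets within the radius, lexicographic order) over every in-mask
center, re-estimating templates and tracking within each sphere and
assigning the mean relative index to the center. Spheres truncated by the
mask below `min_voxels` (default 12) become missing values — small-support
correlation estimates are too unstable to report, and a radius-0
searchlight with a correlation metric is refused outright (a one-voxel
correlation is undefined). Noise normalization, when used, is sphere-local
for the same reason the searchlight exists: noise structure varies over
space.

`run_temporal()` estimates templates per localizer time bin and tracks
them either on the same main-task bin (time course) or on every bin
(temporal generalization matrix, templates from bin *t* applied at
*t'*). The diagonal of the generalization matrix *is* the time course —
both are computed by the same cell function, so the identity is exact, not
approximate.

## Inference

Relative indexes are not Gaussian and their per-subject distributions are
unknown, so inference is nonparametric throughout:

* `wilcoxon_signed_rank()` computes the exact null of the positive-rank
  sum by full sign enumeration (via its generating function, exact under
  tied midranks too) for n <= 25, switching to the
  continuity-and-tie-corrected normal approximation above. Zero
  differences are dropped and counted. One-sample use is appropriate only
  for indexes with a meaningful zero (cv estimators, relative indexes).
* `permutation_test()` offers subject-level label shuffling and
  group-level sign flipping; for n <= 12 subjects the 2^n flips are fully
  enumerated (deterministic, no RNG), otherwise sampled with the add-one
  p-value `(1 + hits) / (1 + n_perm)`.
* `cluster_correct()` thresholds observed and permutation maps (fixed
  statistic cutoff, or the pointwise 1 - alpha null quantile), labels
  connected components (run adjacency in 1D; 6-connectivity default, 26
  optional in 3D) and assigns cluster-level FWE p-values from the null
  distribution of maximal cluster sizes. `fdr_correct()` is
  Benjamini-Hochberg.

Defaults encode a directional pipeline: one-sided tests on relative
indexes (target hypothesized more active), cluster-forming threshold at
uncorrected p < 0.05 from the permutation null. Both are flags, not
constants. The calibration of the whole chain — simulate a true null
(equal target/baseline weights), track, sign-flip, cluster-correct —
is itself a test: over 200 simulated experiments the rejection rate at
alpha = 0.05 must fall inside the exact binomial 95% interval.

## Reliability diagnostics

Differences in activation indexes between templates are interpretable only
if the templates are comparably reliable. `compute_snr()` (mean/SD of an
index distribution), `compute_entropy()` (Shannon entropy of a template's
value histogram, 16 equal-width bins by default over the observed range)
and `compute_correlationability()` (mean Fisher-z-averaged correlation
among run-wise estimates of the same template) quantify this. The SNR
definition — mean over sample standard deviation of the per-observation
similarity values — is one reading of a loosely specified convention;
it is scale-invariant, which is the property that matters for comparing
localizers.

## The simulator: what it emulates, and what it does not

`sim_spec()`/`generate_truth()`/`simulate_localizer()`/`simulate_main_task()`
generate the full study: balanced localizer runs (trial = own template +
noise), main-task chunks (trial = weighted template mixture + noise +
optional per-chunk scalar baseline shift), epoch mode (boxcar activation
inside `active_window`; the window applies to the localizer too, so
temporal-generalization structure is testable on both axes), and volume
mode (templates occupy only an ROI box inside a 3D grid; spatially
correlated noise is sampled exactly via per-axis Kronecker Cholesky
factors of the separable kernel, never by materializing the full V x V
covariance). All draws derive from the spec seed through a splitmix-hashed
sub-seed tree — related analyses never share adjacent raw seeds, which
would correlate their random streams — making every dataset
bit-reproducible.

The simulator is a validation instrument, not a forward model: there is no
hemodynamic response or ERP shape (the boxcar stands in for any temporal
envelope), no physiological or motion artifacts, no autocorrelated noise,
and noise is Gaussian and stationary. Passing tests therefore demonstrate
that the estimators do what they claim under their own assumptions —
unbiasedness, calibration, recovery — not that real data meet those
assumptions.

## Numerical and design choices

* **Shrinkage covariance** (noise model and LDA): target is the diagonal
  of the empirical covariance; the analytic intensity is the summed
  sampling variance of the off-diagonal entries over their summed squares
  (clipped to [0, 1], overridable). At intensity 1 the whitener reduces
  exactly to per-unit SD scaling, so multivariate normalization contains
  univariate normalization as a special case — asserted in the tests.
* **Supertrial grouping** is a seeded random partition within condition x
  run cells, discarding remainders; cell means are invariant to input
  order when the group spans the cell.
* **Smoothing edges** use truncated windows — no data are invented beyond
  the epoch.
* **PCA** is fit on the localizer only and its projection applied to the
  main task, so no main-task information leaks into the template space;
  the retained count is the minimal one reaching the variance fraction.
* **Conventions**: time windows are half-open `[start, end)` on 0-based
  bins; voxel unit ids are 0-based C-order linear indexes; both are
  enforced everywhere they appear (containers, masks, maps).
* **Problem sizes** in the validation battery (V of 30-300, 8-20 trials
  per condition, 200 simulated null experiments, a 20^3 searchlight grid)
  were chosen as the smallest sizes at which the analytic expectations are
  sharp enough to test against; they complete in well under a minute each
  on a single core.

## Known limitations

Within-region comparisons only (templates and main-task patterns must
share their unit support exactly); no preprocessing (realignment,
filtering, artifact rejection) or hemodynamic modeling — patterns enter as
matrices, volumes or epoch containers; the trial-wise GLM is plain least
squares with one regressor per trial, not the iterative single-trial
variant; cross-validated estimators require a chunked main task by
construction and refuse single-chunk designs; and the residual
template-noise bias of the fixed-template cv scheme is documented, not
corrected.
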