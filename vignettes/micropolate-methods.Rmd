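---
title: "Interpolating longitudinal microbiome data: models, evaluation, and design choices"
author: "micropolate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolating longitudinal microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropolate)
```

## The problem

Longitudinal gut-microbiome studies sample individuals irregularly: days or
weeks may separate consecutive stool samples, and time points planned for
comparison across individuals are often simply missing. Downstream analyses
(alignment of series, dynamical modelling, event detection) would benefit
from imputing the community composition at unsampled days. `micropolate`
implements a roster of interpolation methods for per-individual
compositional time series, a leave-one-out framework to score them, and
diagnostics that explain *when* interpolation works: community and taxon
stability, sampling density, and a mixed-effects model that predicts the
accuracy of an interpolation before you trust it.

The unit of data is a `LongitudinalProfile`: one individual's samples-by-taxa
matrix of relative abundances with real-valued time stamps in days (day 0 is
the first sample). Every row lies on the probability simplex. Profiles read
from count tables are renormalized per sample, and the standard
preprocessing (`selectTopTaxa()`) keeps the 30 taxa with the highest mean
relative abundance and sums everything else into a trailing `"others"`
column, so all methods see a fixed 31-taxon composition. The `"others"`
column takes part in all per-taxon analyses by default; `excludeOthers`
flags it out where that matters, since an aggregate column is not a taxon.

## The interpolation roster

All methods map (profile without the target sample, target time) to a
composition on the simplex; `interpolateAt()` dispatches by name.

* **mean / median / last** — per-taxon mean or median over all available
  samples (renormalized, since per-taxon means need not sum to one), or the
  composition of the nearest preceding sample. Mean and median use *all*
  samples, not only past ones.
* **equal** — the uniform null, `1/n` for every taxon. Any method worth
  using must beat it.
* **weighted_average** — convex combination of the two bracketing samples
  with weights inverse to the time distance; convexity keeps it on the
  simplex with no renormalization.
* **knn** — Epanechnikov-kernel K-nearest neighbours in time (default
  `K = 5`). Distances to the target are scaled by the farthest selected
  neighbour, so that neighbour always gets exactly zero weight; `K = 1`
  therefore falls back to uniform weights (i.e. the nearest sample), the
  kernel's limit as the distance spread vanishes. Ties for the K-th slot go
  to the earlier sample, making the method deterministic.
* **spline** — an independent cubic spline per taxon, evaluated at the
  target, negatives clipped to zero, renormalized. We use
  Forsythe–Malcolm–Moler end conditions (`stats::spline`, `method = "fmm"`)
  because they reproduce polynomials up to degree three exactly, which is
  the property our oracle tests pin down; with 3 (2) points the fit
  degrades to the interpolating quadratic (line).
* **glv_mse / mlrr / limits** — the discretized generalized Lotka–Volterra
  model. Over each consecutive pair, `(ln x_i(t+dt) − ln x_i(t))/dt =
  beta_i + sum_j alpha_ij x_j(t)`; stacking pairs gives `F = (A B) Y`.
  Dividing by `dt` accommodates irregular sampling. Zeros are replaced by
  a pseudocount `eps = 1e-6` before logs — this preserves the pair count at
  a bounded influence on `F`. The three estimators are row-wise ordinary
  least squares (minimum-norm via pseudoinverse when the design is rank
  deficient), ridge regression with leave-one-pair-out cross-validated
  penalty (MLRR), and a sparse bootstrap forward-selection scheme (LIMITS).
  Prediction is a single forward Euler step from the nearest preceding
  sample, exponentiated and renormalized; multi-step integration is
  deliberately not used, mirroring the one-step structure of the DBN.
* **dbn_dense / dbn_sparse** — a linear-Gaussian dynamic Bayesian network
  written as a bipartite graph: each taxon at the next sample is a linear
  child of all taxa at the previous sample plus the inter-sample time
  difference. Dense: full-parent ridge regression (intercept unpenalized).
  Sparse: greedy forward parent selection under BIC, at most 3 parents per
  child. This is a self-contained re-implementation of the dense/sparse
  idea, not a port of any conditional-Gaussian network package; structure
  search beyond greedy BIC is out of scope. After a leave-one-out deletion,
  "consecutive" pairs are consecutive among the *remaining* samples, with
  their actual `dt` — the time-difference node is exactly what makes that
  coherent.

### Numerical safeguards

Two safeguards matter in practice and both are documented defaults, not
tunables hidden in the code:

* `predictGLV()` clamps the per-taxon one-step log increment at
  `logRateBound = 5` (about a 150-fold change per step). Real gut taxa do
  not change 150-fold between adjacent samples; increments beyond that
  arise only from degenerate fits — typically when a conditionally present
  taxon flips between absent (pseudocount) and abundant, which turns single
  log-differences into rates of magnitude ~10. The clamp leaves
  well-conditioned fits bit-identical and keeps degenerate ones bounded;
  clamped predictions carry a `"clamped"` attribute.
* LIMITS estimates each bootstrap repetition's coefficients on *all* pairs
  over the support selected on that repetition's 50/50 split. Estimating
  them on the train half instead makes the coordinate-wise median across
  repetitions incoherent whenever the always-included growth and
  self-interaction columns are nearly collinear (weakly excited, stable
  series), producing self-interactions two orders of magnitude off. The
  split drives selection; the full series drives estimation.

## Evaluation framework

`looEvaluate()` removes each interior sample in turn (endpoints are never
targets, so every prediction is an interpolation), refits any trainable
method on the remaining samples — honest leave-one-out, no caching across
omissions — predicts at the omitted time, and scores

* **Bray–Curtis similarity** `1 − sum|x−y| / sum(x+y)` (equivalently
  `sum min(x, y)` on the simplex) against the held-out truth, and
* per-taxon **relative errors** `|real − predicted| / real`, `NaN` where
  the true abundance is zero (excluded from aggregates).

Method failures on a target (e.g. a DBN asked to train on two samples)
become flagged records, never silent drops. `subsampleExperiment()`
emulates sparser studies by Monte-Carlo subsampling: endpoints are always
retained so that the randomly chosen target remains bracketed (the
weighted-average and spline preconditions), and `stratifiedEffects()`
disentangles sample size from sampling gap by holding one fixed in strata.
Correlation analyses (temporal autocorrelation of accuracy,
adjacent-vs-random-context correlations, Shannon-diversity correlation,
between-method agreement) use Pearson or Spearman statistics with the
standard t-approximation p-values and no multiple-testing correction; the
number of random-pairing draws in the context analysis is exposed
(`nDraws`) because a single draw is noisy.

## Stability diagnostics

* `timepointStability()` — the mean of three Bray–Curtis similarities
  around an interior sample: the two preceding samples compared with each
  other, the two succeeding ones, and the nearest preceding vs nearest
  succeeding. The third pair uses the *nearest* flanking samples; the
  sentence structure of the definition would also admit both cross pairs,
  and we fixed the nearest-pair reading.
* `bimodalityCoefficient()` — `beta = (gamma^2 + 1) / (kappa + 3(n−1)^2 /
  ((n−2)(n−3)))` with bias-uncorrected moment estimators and *excess*
  kurtosis `kappa`, which places the standard benchmarks at `beta(uniform)
  → 5/9`, `beta(two-point) → 1`, `beta(normal) → 1/3`; with raw kurtosis
  the formula would not reproduce these reference values. The finite-n term
  in the denominator is the usual small-sample correction.
* `classifyTaxonStability()` — by default `beta > 0.7` marks a taxon
  *non-stable*: a high bimodality coefficient is the signature of
  conditionally rare or strongly fluctuating behaviour (taxa with mean
  beta around 0.73 behave conditionally; core colonizers sit near
  0.42–0.45), and that is the orientation the accuracy contrasts rely on.
  The threshold convention is not universal in the literature, so
  `highIsStable = TRUE` flips it. The comparison is strict: `beta = 0.7`
  is stable.

## The accuracy predictor

`buildAccuracyFeatures()` turns one method's LOO records into a model
table: response `logit(BC)` with accuracies clipped to
`[1e-3, 1 − 1e-3]` before the logit (a BC of exactly 1 is otherwise
unusable; the clip bound is exposed), covariates the gaps to the preceding
and subsequent samples and the logit accuracies of the two temporally
adjacent records *of the same method* — these neighbour accuracies carry
the local-stability signal. Records at an individual's boundary lack a
neighbour accuracy and are dropped. `fitAccuracyLMM()` fits a linear mixed
model with a per-individual random intercept by REML (`lme4`); the
individual's sample count is off by default since it is constant within an
individual and hence absorbed by the random intercept (it can be added, and
arbitrary extra covariates are supported for calibration studies). Wald
`z = estimate/SE` with normal tails provides the per-coefficient tests. A
singular fit — the random-intercept variance collapsing to zero — is kept
and flagged; its fixed effects coincide with ordinary least squares.
Predictor evaluation is grouped by individual (held-out individuals never
contribute to the fit) to avoid leakage through the random intercepts;
`evaluatePredictor()` reports the mean absolute error on the Bray–Curtis
scale and the Spearman correlation between predicted and observed accuracy.

## The synthetic cohort

`simulateCohort()` generates the study conditions every analysis above is
exercised on, so the whole package is testable without any external data.
Per individual:

* sampling times are irregular — Gamma-distributed intervals (shape 3)
  with mean 1.5 days, 20–30 samples;
* 31 taxa (30 named + an `"others"` stand-in) with an equilibrium
  composition drawn log-normally: sd 1.0 in the **adult_stable** regime,
  sd 1.6 in the **infant_successional** regime, reflecting that infant guts
  are dominated by fewer taxa;
* dynamics are the discretized gLV model run generatively: stabilizing
  self-interaction −10, weak random off-diagonal interactions (sd 1), and
  growth rates pinned so the drawn composition is an equilibrium. Process
  noise on the log scale has standard deviation `sd · sqrt(dt)` per step —
  diffusion scaling, so longer sampling gaps accumulate proportionally
  more drift, which is what makes accuracy degrade with gap size. Adults
  use sd 0.12, infants 0.40 per sqrt-day;
* the infant regime replaces the fixed growth-rate vector by a logistic
  hand-off between an "early" and a "late" equilibrium community (width
  12% of the sampling span), producing directed, monotone taxonomic
  turnover like the first year of life without naming specific taxa;
* 6 **conditionally present taxa**, drawn from the lower-abundance half,
  follow a two-state Markov presence process (switch rate 0.12/day); while
  "off" their abundance is exactly zero. This directly yields the
  conditionally-rare, high-bimodality, hard-to-interpolate behaviour the
  stability analyses contrast against core taxa;
* every state is closed to the simplex, as a 16S feature table would be.

These values were fixed once, to make the cohort reproduce the magnitudes
reported for dense adult sampling versus infant cohorts (mean KNN LOO
accuracy ≈ 0.86 adult, ≈ 0.6 infant on the default cohort) and the
qualitative structure: every method more accurate in adults than infants;
KNN at or near the top and always above the equal null; accuracy falling
with the gap to the previous sample at fixed sample size; accuracy
positively correlated with local stability; bimodality negatively
correlated with mean abundance. What the generator does *not* emulate:
sequencing noise and compositional count sparsity beyond the hard on/off
taxa, taxonomic identity, inter-individual taxon sharing (each individual
has its own equilibrium), and perturbations (antibiotics, diet) — so
passing tests say the methods behave as designed under smooth autoregressive
dynamics with succession and conditional presence, not that any method is
validated for perturbed or diseased cohorts.

For analytic oracle tests, `simulateGLVProfile(closure = FALSE)` skips the
simplex closure: on such absolute-abundance series the regression
`F = (A B) Y` holds exactly at zero noise, and the least-squares estimator
must recover the generating parameters to machine precision — the package's
round-trip guarantee. Closure mixes a per-step common factor into all
log-differences, so exact recovery is only defined in this test mode.

## Problem sizes and determinism

The bundled experiments and tests run at deliberately desk-sized scales:
the default cohort is 20 individuals (≈ 465 LOO targets per method), the
closure sweep draws 1000 random leave-one-out predictions per method, LIMITS
uses its default 100 bootstrap splits throughout, and the mixed-model
calibration uses 20 replicates of 20 individuals × 30 records. All
randomness flows through explicit integer seeds: profile-level LOO derives
a per-target sub-seed (so records are independent of evaluation order), the
subsampling experiment derives one seed per (size, replicate), and
`runPipeline()` reruns are byte-identical given equal seeds.

## Known limitations

* gLV inference operates on relative abundances; compositional closure
  distorts the interaction estimates (a well-known limitation), and the
  package makes no attempt at absolute-abundance reconstruction.
* The DBN is linear-Gaussian with lag 1; hybrid discrete/continuous
  networks and longer lags are out of scope.
* The pseudocount `eps = 1e-6` makes absent↔present flips look like
  enormous rates to the gLV family; the log-rate clamp bounds the damage
  but conditionally rare taxa remain poorly served by these models.
* p-values are reported without multiple-testing correction, matching the
  analyses the framework reproduces; treat them as descriptive.
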