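# micropolate

Interpolation and accuracy prediction for longitudinal microbiome data.

Longitudinal 16S studies sample each subject's gut community at irregular
days, and analyses that need a composition at an unsampled time have to
impute it. `micropolate` is for microbiome researchers who want to (i)
interpolate missing samples in per-individual compositional time series,
(ii) know which method to trust, and (iii) predict how accurate a given
interpolation will be before using it.

## What it implements

**Data model.** A `LongitudinalProfile` holds one individual's
samples-by-taxa relative-abundance matrix with day-scale time stamps; every
row lies on the simplex. Standard preprocessing keeps the 30 most abundant
taxa and aggregates the rest into `"others"`.

**Interpolation methods** (all behind `interpolateAt()`): per-taxon
mean/median, last-sample carry-forward, the uniform "equal" null, weighted
average of the bracketing samples, Epanechnikov-kernel K-nearest-neighbours

    x(t) = sum_i 3/4 (1 - u_i^2) y_i,   u_i = |t_i - t| / max_j |t_j - t|,

per-taxon cubic splines with clipping, the discretized generalized
Lotka-Volterra model

    (ln x_i(t+dt) - ln x_i(t)) / dt = beta_i + sum_j alpha_ij x_j(t),
    i.e.  F = (A B) Y,

fitted by least squares (gLV-MSE), cross-validated ridge (MLRR), or sparse
bootstrap forward selection (LIMITS), and dense/sparse linear-Gaussian
dynamic Bayesian networks over consecutive samples.

**Evaluation.** Leave-one-out over interior samples, scored with
Bray-Curtis similarity `1 - sum|x-y|/sum(x+y)` and per-taxon relative
errors; Monte-Carlo subsampling experiments for sample-size and
sampling-gap effects; correlation analyses (temporal autocorrelation,
neighbour context, Shannon diversity, between-method agreement).

**Stability.** Time-point community stability (mean Bray-Curtis among the
surrounding samples), the bimodality coefficient
`beta = (gamma^2 + 1) / (kappa + 3(n-1)^2 / ((n-2)(n-3)))` for taxon
stability, and their correlations with accuracy.

**Accuracy prediction.** A linear mixed model (random intercept per
individual) on logit-transformed accuracy with sampling gaps and the
adjacent targets' accuracies as fixed effects; Wald tests, grouped
(leave-individuals-out) MAE and Spearman evaluation.

**Synthetic cohort.** A seeded generator producing adult-like stable and
infant-like successional individuals with conditionally present (bimodal)
taxa, so every analysis runs end to end without external data.

## Worked example

```r
library(micropolate)

cohort  <- simulateCohort(syntheticConfig())
profile <- cohort$profiles[["adult_01"]]
profile
#> LongitudinalProfile: adult_01 (adult_stable)
#>   29 samples over 43.14 days; 31 taxa
#>   mean interval: 1.541 days

ev <- looEvaluate(profile, "knn")
head(records(ev)[, c("target_time", "bc_similarity", "gap_prev", "gap_next")], 3)
#>   target_time bc_similarity gap_prev gap_next
#> 1    1.481214     0.9490956 1.481214 2.167074
#> 2    3.648288     0.7709748 2.167074 3.089297
#> 3    6.737585     0.5868191 3.089297 1.327431
```

Each row scores one omitted sample: the day it was held out, the
Bray-Curtis similarity between the KNN prediction and the truth (1 =
identical composition), and the gaps to its neighbours — note how the
accuracy drops as the preceding gap grows. Across the whole cohort the
regimes separate cleanly:

```r
recs <- combineRecords(lapply(cohort$profiles, looEvaluate, method = "knn"))
summarizeAccuracy(recs, groupBy = "dataset")
#>               dataset   n n_failed   mean_bc median_bc
#> 1        adult_stable 235        0 0.8715400 0.9273037
#> 2 infant_successional 223        0 0.6278931 0.6887144
```

Stable adult communities interpolate at mean similarity 0.87; successional
infant-like communities at 0.63. The mixed model then predicts per-sample
accuracy from its context:

```r
feats <- buildAccuracyFeatures(recs)
fit   <- fitAccuracyLMM(feats)
fixedEffects(fit)
#>            term   estimate         se          z            p
#> 1   (Intercept)  0.5232115 0.08790027   5.952330 2.643511e-09
#> 2      gap_prev -0.3542442 0.02930804 -12.086930 1.238280e-33
#> 3      gap_next  0.0497527 0.03340645   1.489314 1.364046e-01
#> 4 logit_bc_prev  0.4633331 0.02616042  17.711228 3.434967e-70
#> 5 logit_bc_next  0.4833264 0.02898798  16.673335 2.048387e-62
```

Accuracy at the adjacent targets is by far the strongest predictor (the
community-stability signal), and a longer gap to the preceding sample
costs accuracy. Local stability correlates strongly with accuracy at the
sample level:

```r
stabilityAccuracyCorrelation(lapply(cohort$profiles, looEvaluate, method = "knn"),
                             cohort$profiles, "sample")
#> rho 0.841, p ~ 0, n = 418
```

A full run — preprocessing, all-method LOO, stability tables, subsampling,
accuracy models, manifest — is one call:

```r
runPipeline(pipelineConfig(accuracyModel = TRUE), "run_dir")
```

or from a shell, `Rscript inst/scripts/micropolate-pipeline.R --out run_dir`.

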