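#' Naive interpolation: per-taxon mean, median, or preceding sample
#'
#' `mean` and `median` interpolate each taxon's abundance by its mean or
#' median across all available samples; because per-taxon means or medians
#' need not sum to one, the result is renormalized. `last` returns the
#' composition of the sample immediately preceding the target time.
#'
#' @param profile a [LongitudinalProfile-class] (without the target sample).
#' @param targetTime day at which to interpolate.
#' @param mode one of `"mean"`, `"median"`, `"last"`.
#' @return a named composition vector on the simplex.
#' @export
interpolateNaive <- function(profile, targetTime, mode = c("mean", "median", "last")) {
  mode <- match.arg(mode)
  ab <- abundanceMatrix(profile)
  if (mode == "last") {
    prev <- which(sampleTimes(profile) < targetTime)
    if (!length(prev))
      stop("no sample precedes the target time; 'last' cannot extrapolate backwards")
    return(ab[max(prev), ])
  }
  v <- if (mode == "mean") colMeans(ab) else apply(ab, 2, stats::median)
  normalizeComposition(v)
}

#' The uniform "equal" null interpolation
#'
#' Assigns every taxon (including the `"others"` category) the same
#' abundance `1 / n_taxa`. Serves as the null reference any informative
#' method should beat.
#'
#' @param nTaxa number of taxa.
#' @param taxa optional labels for the output.
#' @return a composition vector with all entries `1 / nTaxa`.
#' @export
interpolateEqual <- function(nTaxa, taxa = NULL) {
  stopifnot(nTaxa >= 1)
  out <- rep(1 / nTaxa, nTaxa)
  if (!is.null(taxa)) names(out) <- taxa
  out
}

#' Weighted average of the two bracketing samples
#'
#' Interpolates at time `t` as the convex combination of the closest
#' preceding sample `x1` (at `t1`) and closest subsequent sample `x2`
#' (at `t2`), with weights inverse to the time distance:
#' `((t2 - t) x1 + (t - t1) x2) / (t2 - t1)`. Convexity keeps the result on
#' the simplex without renormalization.
#'
#' @inheritParams interpolateNaive
#' @export
interpolateWeightedAverage <- function(profile, targetTime) {
  tms <- sampleTimes(profile)
  before <- which(tms < targetTime)
  after <- which(tms > targetTime)
  if (!length(before) || !length(after))
    stop("weighted average needs samples strictly before and after the target")
  i1 <- max(before); i2 <- min(after)
  t1 <- tms[i1]; t2 <- tms[i2]
  ab <- abundanceMatrix(profile)
  ((t2 - targetTime) * ab[i1, ] + (targetTime - t1) * ab[i2, ]) / (t2 - t1)
}

#' Epanechnikov-kernel K-nearest-neighbours interpolation
#'
#' Selects the `K` samples closest in time to the target (on either side)
#' and combines their compositions with Epanechnikov weights
#' `3/4 (1 - u_i^2)`, where `u_i = |t_i - t| / max_j |t_j - t|` is the
#' time distance scaled by the farthest selected neighbour. The farthest
#' neighbour therefore always receives exactly zero weight; with `K = 1`
#' (or when all selected distances are equal, so every weight vanishes) the
#' method falls back to uniform weights over the selected neighbours — the
#' limit of the kernel as the distance spread shrinks to zero. The combined
#' composition is renormalized to the simplex.
#'
#' Distance ties competing for the K-th slot are resolved in favour of the
#' earlier sample, making the selection deterministic.
#'
#' @inheritParams interpolateNaive
#' @param K number of neighbours (default 5).
#' @export
interpolateKNN <- function(profile, targetTime, K = 5) {
  stopifnot(K >= 1)
  tms <- sampleTimes(profile)
  d <- abs(tms - targetTime)
  sel <- order(d, tms)[seq_len(min(K, length(tms)))]
  dmax <- max(d[sel])
  if (dmax == 0) stop("target time coincides with an available sample")
  u <- d[sel] / dmax
  w <- 0.75 * (1 - u^2)
  if (sum(w) <= 0) w <- rep(1, length(sel))   # all neighbours equidistant
  ab <- abundanceMatrix(profile)
  normalizeComposition(drop(w %*% ab[sel, , drop = FALSE]))
}

#' Cubic-spline interpolation with clipping
#'
#' Fits a cubic spline per taxon through its abundance series (exact-cubic
#' Forsythe-Malcolm-Moler end conditions, which reproduce polynomials up to
#' degree three exactly) and evaluates it at the target time; negative
#' values are clipped to zero and the composition is renormalized. With
#' only 3 (2) available samples the per-taxon fit degrades to the
#' interpolating quadratic (linear) — a cubic is not determined by fewer
#' than 4 points.
#'
#' @inheritParams interpolateNaive
#' @export
interpolateSpline <- function(profile, targetTime) {
  tms <- sampleTimes(profile)
  if (targetTime < min(tms) || targetTime > max(tms))
    stop("spline interpolation requires the target inside the sampled interval")
  ab <- abundanceMatrix(profile)
  n <- length(tms)
  raw <- if (n >= 4L) {
    apply(ab, 2, function(y)
      stats::spline(tms, y, xout = targetTime, method = "fmm")$y)
  } else {
    # exact polynomial through 2 or 3 points
    apply(ab, 2, function(y) {
      co <- pracma::polyfit(tms, y, n - 1L)
      pracma::polyval(co, targetTime)
    })
  }
  clipped <- pmax(raw, 0)
  if (sum(clipped) <= 0)
    stop("degenerate spline: all taxa clipped to zero at t = ", targetTime)
  normalizeComposition(clipped)
}

# ---- method registry ---------------------------------------------------

#' Interpolation method registry
#'
#' Names of all interpolation methods known to [interpolateAt()] and
#' [looEvaluate()].
#'
#' @return character vector of method names.
#' @export
interpolationMethods <- function() {
  c("mean", "median", "last", "equal", "weighted_average", "knn", "spline",
    "glv_mse", "mlrr", "limits", "dbn_dense", "dbn_sparse")
}

#' Interpolate a profile at a target time with any registered method
#'
#' Dispatches to the individual interpolators by name; trainable methods
#' (gLV family, DBN) are fitted on `profile` and then predict forward from
#' the sample preceding `targetTime`. Method parameters are passed through
#' `params`.
#'
#' @param profile a [LongitudinalProfile-class]; must not contain a sample
#'   at `targetTime`.
#' @param targetTime day at which to interpolate.
#' @param method a method name from [interpolationMethods()].
#' @param params named list of method parameters. Recognized entries:
#'   `K` (knn, default 5); `epsilon` (gLV pseudocount, default 1e-6);
#'   `lambda` (mlrr ridge penalty; `NULL` selects it by cross-validation);
#'   `nBootstrap`, `improvementThreshold` (limits); `ridge`, `maxParents`
#'   (dbn).
#' @param seed optional integer seed used by the stochastic LIMITS
#'   estimator; all other methods are deterministic.
#' @return a composition vector on the simplex, aligned to `taxa(profile)`.
#' @export
interpolateAt <- function(profile, targetTime, method, params = list(),
                          seed = NULL) {
  stopifnot(is(profile, "LongitudinalProfile"))
  method <- match.arg(method, interpolationMethods())
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  switch(method,
    mean = interpolateNaive(profile, targetTime, "mean"),
    median = interpolateNaive(profile, targetTime, "median"),
    last = interpolateNaive(profile, targetTime, "last"),
    equal = interpolateEqual(nTaxa(profile), taxa(profile)),
    weighted_average = interpolateWeightedAverage(profile, targetTime),
    knn = interpolateKNN(profile, targetTime, K = p("K", 5)),
    spline = interpolateSpline(profile, targetTime),
    glv_mse = ,
    mlrr = ,
    limits = {
      eps <- p("epsilon", 1e-6)
      mats <- buildGLVRegression(profile, epsilon = eps)
      fit <- switch(method,
        glv_mse = fitGLVMSE(mats),
        mlrr = fitGLVMLRR(mats, lambda = params$lambda),
        limits = fitGLVLIMITS(mats,
                              nBootstrap = p("nBootstrap", 100),
                              improvementThreshold = p("improvementThreshold", 1e-3),
                              seed = seed))
      glvForecast(profile, fit, targetTime, epsilon = eps)
    },
    dbn_dense = ,
    dbn_sparse = {
      mode <- sub("^dbn_", "", method)
      model <- fitDBN(profile, mode = mode,
                      maxParents = p("maxParents", 3),
                      ridge = p("ridge", 1e-3))
      dbnForecast(profile, model, targetTime)
    }
  )
}
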