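#' Build the discretized gLV regression matrices
#'
#' Discretizing the generalized Lotka-Volterra equations over consecutive
#' sample pairs gives, for each taxon i and interval (t, t + dt),
#' `(ln x_i(t+dt) - ln x_i(t)) / dt = beta_i + sum_j alpha_ij x_j(t)`,
#' i.e. the matrix regression `F = (A B) Y` where the columns of `F` hold
#' the time-normalized log-abundance changes and the columns of `Y` the
#' abundances at the interval starts plus a constant-one row. Dividing by
#' the interval length makes irregular sampling usable. Zero abundances are
#' replaced by the pseudocount `epsilon` before taking logs.
#'
#' @param profile a [LongitudinalProfile-class] with at least 2 samples, or
#'   — for analytic validation on absolute abundances (see
#'   [simulateGLVProfile()] with `closure = FALSE`) — a samples-by-taxa
#'   matrix, in which case `times` must be supplied, or a list with
#'   elements `abundances` and `times`.
#' @param epsilon pseudocount substituted for zero abundances (default 1e-6).
#' @param times sampling days when `profile` is a plain matrix.
#' @return a [GLVRegression-class] with one column per consecutive pair.
#' @export
buildGLVRegression <- function(profile, epsilon = 1e-6, times = NULL) {
  stopifnot(epsilon > 0)
  if (is(profile, "LongitudinalProfile")) {
    ab <- abundanceMatrix(profile)
    tms <- sampleTimes(profile)
  } else if (is.list(profile) && !is.null(profile$abundances)) {
    ab <- as.matrix(profile$abundances)
    tms <- profile$times
  } else {
    if (is.null(times)) stop("supply 'times' with a plain abundance matrix")
    ab <- as.matrix(profile)
    tms <- times
  }
  if (is.null(colnames(ab)))
    colnames(ab) <- paste0("taxon_", seq_len(ncol(ab)))
  if (any(diff(tms) <= 0)) stop("times must be strictly increasing")
  n <- nrow(ab)
  if (n < 2L) stop("need at least 2 samples to form a pair")
  d <- diff(tms)
  lx <- log(pmax(ab, epsilon))
  F <- t((lx[-1L, , drop = FALSE] - lx[-n, , drop = FALSE]) / d)
  Y <- rbind(t(ab[-n, , drop = FALSE]), rep(1, n - 1L))
  dimnames(F) <- NULL; dimnames(Y) <- NULL
  new("GLVRegression", F = F, Y = Y, pairDeltas = as.numeric(d),
      taxa = colnames(ab))
}

glvFromTheta <- function(theta, taxa, estimator) {
  n <- length(taxa)
  A <- theta[, seq_len(n), drop = FALSE]
  dimnames(A) <- list(taxa, taxa)
  new("GLVModel", A = A, B = as.numeric(theta[, n + 1L]), taxa = taxa,
      estimator = estimator)
}

#' Least-squares (MSE) estimator of the gLV parameters
#'
#' Solves `F = (A B) Y` row by row by ordinary least squares. When `Y` is
#' rank deficient (fewer pairs than taxa + 1, or duplicated columns) the
#' minimum-norm solution is returned via the Moore-Penrose pseudoinverse,
#' unless `strict = TRUE`, in which case rank deficiency is an error.
#'
#' @param mats a [GLVRegression-class].
#' @param strict error on a rank-deficient design instead of returning the
#'   minimum-norm solution.
#' @return a [GLVModel-class].
#' @export
fitGLVMSE <- function(mats, strict = FALSE) {
  stopifnot(is(mats, "GLVRegression"))
  Y <- mats@Y
  r <- qr(Y)$rank
  if (strict && r < nrow(Y))
    stop("rank-deficient gLV design (rank ", r, " < ", nrow(Y), ")")
  theta <- mats@F %*% MASS::ginv(Y)
  glvFromTheta(theta, mats@taxa, "mse")
}

#' Ridge (MLRR) estimator of the gLV parameters
#'
#' Maximum-likelihood unconstrained ridge regression: per-row solution of
#' the penalized normal equations, `(A B) = F Y' (Y Y' + lambda I)^-1`.
#' When `lambda` is `NULL` it is selected by leave-one-pair-out
#' cross-validation over a logarithmic grid (`10^-8 ... 10^2`), minimizing
#' the squared prediction error of the held-out column of `F`.
#'
#' @param mats a [GLVRegression-class].
#' @param lambda non-negative ridge penalty, or `NULL` to cross-validate.
#' @param lambdaGrid candidate penalties for cross-validation.
#' @return a [GLVModel-class]; the penalty actually used is recorded in the
#'   object's `"lambda"` attribute.
#' @export
fitGLVMLRR <- function(mats, lambda = NULL,
                       lambdaGrid = 10^seq(-8, 2, by = 1)) {
  stopifnot(is(mats, "GLVRegression"))
  Y <- mats@Y; F <- mats@F
  q <- nrow(Y)
  solveRidge <- function(F, Y, lam) {
    F %*% t(Y) %*% solve(Y %*% t(Y) + lam * diag(q))
  }
  if (is.null(lambda)) {
    p <- ncol(Y)
    if (p < 3L) {
      lambda <- lambdaGrid[1L]
    } else {
      cvErr <- vapply(lambdaGrid, function(lam) {
        err <- 0
        for (j in seq_len(p)) {
          th <- tryCatch(solveRidge(F[, -j, drop = FALSE], Y[, -j, drop = FALSE], lam),
                         error = function(e) NULL)
          if (is.null(th)) return(Inf)
          err <- err + sum((F[, j] - th %*% Y[, j])^2)
        }
        err
      }, numeric(1))
      lambda <- lambdaGrid[which.min(cvErr)]
    }
  }
  theta <- if (lambda == 0) F %*% MASS::ginv(Y) else solveRidge(F, Y, lambda)
  out <- glvFromTheta(theta, mats@taxa, "mlrr")
  attr(out, "lambda") <- lambda
  out
}

#' Sparse bootstrap-aggregated (LIMITS) estimator of the gLV parameters
#'
#' Per-taxon forward stepwise regression in the spirit of the LIMITS
#' algorithm: the model always contains the intrinsic growth rate and the
#' taxon's self-interaction; on each of `nBootstrap` random 50/50 splits of
#' the sample pairs, the covariate that most reduces the out-of-bag
#' prediction error is added repeatedly until the relative error improvement
#' drops below `improvementThreshold`. Each repetition's coefficients are
#' then re-estimated on all pairs over its selected support (the split only
#' drives selection, so the per-coordinate medians stay jointly coherent on
#' weakly excited, near-stationary series), and the final coefficients are
#' the element-wise median over the repetitions; never-selected entries are
#' exactly zero.
#'
#' @param mats a [GLVRegression-class] with at least 3 pairs.
#' @param nBootstrap number of bootstrap splits (default 100).
#' @param improvementThreshold minimal relative out-of-bag error improvement
#'   to accept a covariate (default 1e-3).
#' @param seed optional integer seed for the split randomness.
#' @return a [GLVModel-class] with a sparse interaction matrix.
#' @export
fitGLVLIMITS <- function(mats, nBootstrap = 100, improvementThreshold = 1e-3,
                         seed = NULL) {
  stopifnot(is(mats, "GLVRegression"))
  Y <- mats@Y; F <- mats@F
  p <- ncol(Y); q <- nrow(Y); n <- nrow(F)
  if (p < 3L) stop("LIMITS needs at least 3 sample pairs")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  nTrain <- max(2L, floor(p / 2))
  # pre-drawn split memberships so R's RNG governs the C++ routine
  splits <- matrix(0L, p, nBootstrap)
  for (b in seq_len(nBootstrap)) splits[sample.int(p, nTrain), b] <- 1L
  theta <- cpp_limits_fit(t(Y), F, splits, improvementThreshold)
  glvFromTheta(theta, mats@taxa, "limits")
}

#' One-step gLV forecast from a known composition
#'
#' Single forward Euler step of the discretized gLV model on the log scale:
#' `ln x(t + dt) = ln x(t) + dt (B + A x(t))`, followed by exponentiation
#' and renormalization to the simplex. The per-taxon log increment is
#' clamped to `|dt (B + A x)| <= logRateBound`: the default bound of 5
#' caps the implied change of any taxon at about 150-fold per step, a
#' ceiling that real gut communities do not cross between samples and that
#' only fits degenerate enough to diverge (weakly excited or zero-inflated
#' series) ever reach. Clamping is reported via the `"clamped"` attribute.
#'
#' @param params a [GLVModel-class].
#' @param previousSample composition vector at the step start.
#' @param deltaT positive time step (days).
#' @param epsilon pseudocount for zero abundances before the log.
#' @param logRateBound clamp on the absolute log increment (default 5).
#' @return a composition vector on the simplex.
#' @export
predictGLV <- function(params, previousSample, deltaT, epsilon = 1e-6,
                       logRateBound = 5) {
  stopifnot(is(params, "GLVModel"), deltaT > 0)
  if (length(previousSample) != length(params@taxa))
    stop("composition/model dimension mismatch")
  rate <- deltaT * (params@B + drop(params@A %*% previousSample))
  clamped <- any(abs(rate) > logRateBound)
  rate <- pmin(pmax(rate, -logRateBound), logRateBound)
  lx <- log(pmax(previousSample, epsilon)) + rate
  out <- normalizeComposition(exp(lx - max(lx)))
  names(out) <- params@taxa
  attr(out, "clamped") <- clamped
  out
}

# fit-then-forecast helper: step forward from the nearest preceding sample
glvForecast <- function(profile, fit, targetTime, epsilon = 1e-6) {
  tms <- sampleTimes(profile)
  prev <- which(tms < targetTime)
  if (!length(prev)) stop("gLV forecast needs a sample preceding the target")
  i <- max(prev)
  out <- predictGLV(fit, abundanceMatrix(profile)[i, ], targetTime - tms[i],
                    epsilon = epsilon)
  attr(out, "clamped") <- NULL
  out
}

setMethod("show", "GLVModel", function(object) {
  cat("GLVModel (", object@estimator, "): ", length(object@taxa),
      " taxa\n", sep = "")
  cat("  interaction matrix sparsity:",
      format(mean(object@A == 0), digits = 3), "\n")
})

#' Write gLV parameters to a delimited file
#'
#' Serializes the interaction matrix with the growth-rate vector appended as
#' a final `growth_rate` column, taxa-labelled.
#'
#' @param params a [GLVModel-class].
#' @param path output path.
#' @param sep field separator.
#' @export
writeGLVModel <- function(params, path, sep = "\t") {
  m <- cbind(params@A, growth_rate = params@B)
  df <- data.frame(taxon = params@taxa, m, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
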