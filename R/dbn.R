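#' Fit a linear-Gaussian dynamic Bayesian network
#'
#' The network is bipartite: the parents are the taxa abundances at one
#' sample plus the time difference to the next sample, and the children are
#' the taxa abundances at that next sample. Training pairs are all
#' consecutive pairs among the available samples (after a leave-one-out
#' deletion, the samples flanking the hole pair up with their actual time
#' difference). In `dense` mode every child is regressed on all parents
#' with a ridge penalty (intercept unpenalized); in `sparse` mode each
#' child's parents are chosen by greedy forward selection under BIC, capped
#' at `maxParents`.
#'
#' @param profile a [LongitudinalProfile-class] with at least 3 samples.
#' @param mode `"dense"` or `"sparse"`.
#' @param maxParents sparse-mode cap on parents per child (default 3).
#' @param ridge dense-mode ridge penalty (default 1e-3).
#' @return a [DBNModel-class].
#' @export
fitDBN <- function(profile, mode = c("dense", "sparse"), maxParents = 3,
                   ridge = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(is(profile, "LongitudinalProfile"), ridge >= 0)
  ab <- abundanceMatrix(profile)
  tms <- sampleTimes(profile)
  n <- nrow(ab); nt <- ncol(ab)
  if (n < 3L) stop("DBN fitting needs at least 3 samples (2 pairs)")
  prev <- ab[-n, , drop = FALSE]
  nxt <- ab[-1L, , drop = FALSE]
  dt <- diff(tms)
  X <- cbind(intercept = 1, prev, dt = dt)
  coefs <- matrix(0, nt, nt + 2L,
                  dimnames = list(colnames(ab), c("intercept", colnames(ab), "dt")))
  parentSets <- vector("list", nt)
  names(parentSets) <- colnames(ab)
  vars <- numeric(nt)
  if (mode == "dense") {
    pen <- diag(c(0, rep(1, nt + 1L)))   # intercept unpenalized
    beta <- solve(crossprod(X) + ridge * pen, crossprod(X, nxt))
    coefs[] <- t(beta)
    res <- nxt - X %*% beta
    df <- max(1, nrow(X) - min(nrow(X), nt + 2L))
    vars <- pmax(colSums(res^2) / df, 1e-12)
    for (j in seq_len(nt)) parentSets[[j]] <- c(colnames(ab), "dt")
  } else {
    for (j in seq_len(nt)) {
      fit <- cpp_greedy_bic(X, nxt[, j], as.integer(maxParents))
      coefs[j, ] <- fit$coef
      sel <- fit$selected + 1L            # 0-based -> 1-based
      parentSets[[j]] <- colnames(X)[setdiff(sel, 1L)]
      vars[j] <- max(fit$sigma2, 1e-12)
    }
  }
  new("DBNModel", mode = mode, coefficients = coefs,
      parentSets = parentSets, noiseVariances = vars,
      taxa = colnames(ab), maxParents = as.numeric(maxParents))
}

#' Predict the next composition with a fitted DBN
#'
#' Per-child linear prediction from the previous sample's composition and
#' the time difference; negative predictions are clipped to zero and the
#' result is renormalized to the simplex.
#'
#' @param model a [DBNModel-class].
#' @param previousSample composition vector aligned to the model's taxa.
#' @param deltaT positive time difference (days) to the predicted sample.
#' @return a composition vector on the simplex.
#' @export
predictDBN <- function(model, previousSample, deltaT) {
  stopifnot(is(model, "DBNModel"), deltaT > 0)
  if (length(previousSample) != length(model@taxa))
    stop("composition/model dimension mismatch")
  x <- c(1, as.numeric(previousSample), deltaT)
  raw <- drop(model@coefficients %*% x)
  clipped <- pmax(raw, 0)
  if (sum(clipped) <= 0)
    stop("all DBN predictions non-positive; cannot normalize")
  out <- normalizeComposition(clipped)
  names(out) <- model@taxa
  out
}

# fit-then-forecast helper mirroring glvForecast()
dbnForecast <- function(profile, model, targetTime) {
  tms <- sampleTimes(profile)
  prev <- which(tms < targetTime)
  if (!length(prev)) stop("DBN forecast needs a sample preceding the target")
  i <- max(prev)
  predictDBN(model, abundanceMatrix(profile)[i, ], targetTime - tms[i])
}

setMethod("show", "DBNModel", function(object) {
  cat("DBNModel (", object@mode, "): ", length(object@taxa),
      " child taxa\n", sep = "")
  cat("  mean parents per child:",
      format(mean(vapply(object@parentSets, length, 1L)), digits = 3), "\n")
})
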