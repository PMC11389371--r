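#' @import methods
NULL

#' Longitudinal compositional profile of one individual
#'
#' The central container of the package: one individual's time-stamped
#' relative-abundance matrix. Rows are samples (ordered by time, in days
#' since the first sample), columns are taxa. Every row lies on the simplex:
#' entries are non-negative and sum to one. After preprocessing with
#' [selectTopTaxa()] the last column is the aggregated `"others"` category,
#' so all downstream methods see a fixed taxon set.
#'
#' @slot individualId single character label for the individual.
#' @slot dataset single character label grouping individuals into cohorts or
#'   studies (used by the neighbour-context analyses); may be `NA`.
#' @slot times strictly increasing numeric vector of sampling days.
#' @slot abundances numeric matrix `[n_samples x n_taxa]` of relative
#'   abundances with taxon names as column names.
#'
#' @seealso [LongitudinalProfile()] for the user-facing constructor.
#' @export
setClass("LongitudinalProfile",
  representation(
    individualId = "character",
    dataset      = "character",
    times        = "numeric",
    abundances   = "matrix"
  )
)

setValidity("LongitudinalProfile", function(object) {
  msgs <- character(0)
  ab <- object@abundances
  if (length(object@individualId) != 1L)
    msgs <- c(msgs, "individualId must be a single label")
  if (length(object@dataset) != 1L)
    msgs <- c(msgs, "dataset must be a single label (possibly NA)")
  if (nrow(ab) < 2L)
    msgs <- c(msgs, "a profile needs at least 2 samples")
  if (length(object@times) != nrow(ab))
    msgs <- c(msgs, "length(times) must equal nrow(abundances)")
  if (any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (is.null(colnames(ab)) || anyDuplicated(colnames(ab)))
    msgs <- c(msgs, "abundances must have unique taxon column names")
  if (any(ab < 0))
    msgs <- c(msgs, "abundances must be non-negative")
  rs <- rowSums(ab)
  if (any(abs(rs - 1) > 1e-9))
    msgs <- c(msgs, "every sample row must sum to 1 (within 1e-9)")
  if (length(msgs)) msgs else TRUE
})

#' Regression matrices of the discretized generalized Lotka-Volterra model
#'
#' Holds the design of the per-interval regression `F = (A B) Y`: `F` stacks
#' the time-normalized log-abundance changes of every taxon over every
#' consecutive sample pair, and `Y` stacks the abundances at the interval
#' starts plus a final all-ones row carrying the intrinsic growth-rate term.
#'
#' @slot F numeric matrix `[n_taxa x n_pairs]` of `(ln x(t+dt) - ln x(t))/dt`.
#' @slot Y numeric matrix `[(n_taxa + 1) x n_pairs]`; last row is all ones.
#' @slot pairDeltas positive numeric vector of interval lengths (days).
#' @slot taxa character vector of taxon labels (rows of `F`).
#' @export
setClass("GLVRegression",
  representation(F = "matrix", Y = "matrix", pairDeltas = "numeric",
                 taxa = "character")
)

setValidity("GLVRegression", function(object) {
  msgs <- character(0)
  if (ncol(object@F) != ncol(object@Y))
    msgs <- c(msgs, "F and Y must have the same number of columns")
  if (nrow(object@Y) != nrow(object@F) + 1L)
    msgs <- c(msgs, "Y must have one more row than F (the all-ones row)")
  if (nrow(object@Y) >= 1L && any(object@Y[nrow(object@Y), ] != 1))
    msgs <- c(msgs, "last row of Y must be all ones")
  if (length(object@pairDeltas) != ncol(object@F))
    msgs <- c(msgs, "pairDeltas must have one entry per column")
  if (any(object@pairDeltas <= 0))
    msgs <- c(msgs, "pairDeltas must be positive")
  if (length(object@taxa) != nrow(object@F))
    msgs <- c(msgs, "taxa must label the rows of F")
  if (length(msgs)) msgs else TRUE
})

#' Fitted generalized Lotka-Volterra parameters
#'
#' @slot A interaction matrix `[n_taxa x n_taxa]`; `A[i, j]` is the per-day,
#'   per-unit-abundance effect of taxon `j` on the log-growth of taxon `i`.
#' @slot B intrinsic growth-rate vector (per day).
#' @slot taxa taxon labels.
#' @slot estimator label of the estimator that produced the fit
#'   (`"mse"`, `"mlrr"`, `"limits"`).
#' @export
setClass("GLVModel",
  representation(A = "matrix", B = "numeric", taxa = "character",
                 estimator = "character")
)

setValidity("GLVModel", function(object) {
  msgs <- character(0)
  n <- length(object@taxa)
  if (!all(dim(object@A) == c(n, n)))
    msgs <- c(msgs, "A must be n_taxa x n_taxa")
  if (length(object@B) != n)
    msgs <- c(msgs, "B must have one entry per taxon")
  if (!all(is.finite(object@A)) || !all(is.finite(object@B)))
    msgs <- c(msgs, "A and B must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Linear-Gaussian dynamic Bayesian network over consecutive samples
#'
#' A bipartite model: each taxon at the next sample is a linear-Gaussian
#' child of the taxa at the previous sample plus the inter-sample time
#' difference. The dense variant regresses every child on all parents with a
#' ridge penalty; the sparse variant selects at most `maxParents` parents per
#' child by greedy forward BIC search.
#'
#' @slot mode `"dense"` or `"sparse"`.
#' @slot coefficients matrix `[n_taxa x (n_taxa + 2)]`; columns are
#'   intercept, one per parent taxon, and the time difference.
#' @slot parentSets list, per child, of the names of its selected parents
#'   (excluding the intercept).
#' @slot noiseVariances per-child residual variances (positive).
#' @slot taxa taxon labels.
#' @slot maxParents cap on the sparse parent-set size.
#' @export
setClass("DBNModel",
  representation(mode = "character", coefficients = "matrix",
                 parentSets = "list", noiseVariances = "numeric",
                 taxa = "character", maxParents = "numeric")
)

setValidity("DBNModel", function(object) {
  msgs <- character(0)
  n <- length(object@taxa)
  if (!object@mode %in% c("dense", "sparse"))
    msgs <- c(msgs, "mode must be 'dense' or 'sparse'")
  if (!all(dim(object@coefficients) == c(n, n + 2L)))
    msgs <- c(msgs, "coefficients must be n_taxa x (n_taxa + 2)")
  if (length(object@parentSets) != n)
    msgs <- c(msgs, "one parent set per child taxon required")
  if (length(object@noiseVariances) != n || any(object@noiseVariances <= 0))
    msgs <- c(msgs, "noiseVariances must be positive, one per child")
  if (object@mode == "sparse" &&
      any(vapply(object@parentSets, length, 1L) > object@maxParents))
    msgs <- c(msgs, "sparse parent sets must respect maxParents")
  if (length(msgs)) msgs else TRUE
})

#' Leave-one-out evaluation of one interpolation method on one profile
#'
#' @slot records data.frame with one row per interior target sample:
#'   `individual_id`, `dataset`, `method`, `target_index`, `target_time`,
#'   `bc_similarity`, `gap_prev`, `gap_next`, `n_samples_available`,
#'   `failed`, `message`.
#' @slot predicted matrix `[n_records x n_taxa]` of predicted compositions
#'   (NA rows where the method failed).
#' @slot actual matrix of the held-out true compositions.
#' @slot relativeErrors matrix of per-taxon relative errors
#'   `|real - predicted| / real` (NaN where the true abundance is zero).
#' @slot taxa taxon labels.
#' @export
setClass("LooEvaluation",
  representation(records = "data.frame", predicted = "matrix",
                 actual = "matrix", relativeErrors = "matrix",
                 taxa = "character")
)

#' Fitted mixed-effects predictor of interpolation accuracy
#'
#' @slot fixedEffects data.frame with columns `term`, `estimate`, `se`,
#'   `z`, `p` (Wald statistics from the normal approximation).
#' @slot randomInterceptVariance variance of the per-individual intercept.
#' @slot residualVariance residual variance on the logit scale.
#' @slot converged logical convergence flag.
#' @slot singular logical; `TRUE` when the random-intercept variance
#'   collapsed to (numerical) zero.
#' @slot ranef named numeric vector of per-individual intercept deviations.
#' @slot clipEpsilon the logit clipping bound used to build the response.
#' @slot terms character vector of fixed-effect covariate names.
#' @export
setClass("AccuracyModelFit",
  representation(fixedEffects = "data.frame",
                 randomInterceptVariance = "numeric",
                 residualVariance = "numeric",
                 converged = "logical", singular = "logical",
                 ranef = "numeric", clipEpsilon = "numeric",
                 terms = "character")
)
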