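logit <- function(p) log(p / (1 - p))
invLogit <- function(x) 1 / (1 + exp(-x))

#' Build the feature table for the accuracy-prediction model
#'
#' From the leave-one-out records of one method, builds one row per target
#' with the covariates of the mixed-effects accuracy model: the time gaps
#' to the preceding and subsequent samples, the logit-transformed accuracy
#' of the temporally adjacent records (same individual, same method), the
#' individual's sample count, and the logit-transformed accuracy as the
#' response. Accuracies are clipped to `[eps, 1 - eps]` before the logit.
#' Boundary records, which lack a preceding or subsequent accuracy, are
#' dropped; individuals contributing fewer than 3 records are excluded
#' with a warning.
#'
#' @param recs combined records of a single method (see
#'   [combineRecords()]), or a [LooEvaluation-class].
#' @param clipEpsilon logit clipping bound (default 1e-3).
#' @return data.frame with columns `individual_id`, `target_time`,
#'   `n_samples`, `gap_prev`, `gap_next`, `logit_bc_prev`, `logit_bc_next`,
#'   `bc_similarity`, `logit_bc`.
#' @export
buildAccuracyFeatures <- function(recs, clipEpsilon = 1e-3) {
  if (is(recs, "LooEvaluation")) recs <- records(recs)
  stopifnot(length(unique(recs$method)) == 1L)
  recs <- recs[!recs$failed & !is.na(recs$bc_similarity), , drop = FALSE]
  clip <- function(p) pmin(pmax(p, clipEpsilon), 1 - clipEpsilon)
  out <- list()
  for (id in unique(recs$individual_id)) {
    d <- recs[recs$individual_id == id, , drop = FALSE]
    d <- d[order(d$target_time), , drop = FALSE]
    if (nrow(d) < 3L) {
      warning("individual '", id, "' has fewer than 3 records; excluded")
      next
    }
    lb <- logit(clip(d$bc_similarity))
    k <- seq(2L, nrow(d) - 1L)
    out[[id]] <- data.frame(
      individual_id = id,
      target_time = d$target_time[k],
      n_samples = d$n_samples_available[k] + 1L,
      gap_prev = d$gap_prev[k],
      gap_next = d$gap_next[k],
      logit_bc_prev = lb[k - 1L],
      logit_bc_next = lb[k + 1L],
      bc_similarity = d$bc_similarity[k],
      logit_bc = lb[k],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no individual with at least 3 records")
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(res, "clipEpsilon") <- clipEpsilon
  res
}

#' Fit the mixed-effects accuracy predictor
#'
#' Restricted-maximum-likelihood fit of
#' `logit_bc ~ gap_prev + gap_next + logit_bc_prev + logit_bc_next`
#' (optionally `+ n_samples`) with a per-individual random intercept, via
#' `lme4::lmer`. A singular fit (random-intercept variance collapsing to
#' zero) is kept, flagged, and warned about — the fixed effects then
#' coincide with ordinary least squares.
#'
#' @param features a feature table from [buildAccuracyFeatures()].
#' @param includeNSamples add the individual's sample count as a covariate
#'   (default `FALSE`: it is constant within an individual, hence absorbed
#'   by the random intercept).
#' @param extraTerms names of additional covariate columns of `features` to
#'   include as fixed effects (e.g. for calibration experiments).
#' @return an [AccuracyModelFit-class].
#' @export
fitAccuracyLMM <- function(features, includeNSamples = FALSE,
                           extraTerms = character()) {
  stopifnot(nrow(features) >= 10L,
            length(unique(features$individual_id)) >= 2L)
  terms <- c("gap_prev", "gap_next", "logit_bc_prev", "logit_bc_next")
  if (includeNSamples) terms <- c("n_samples", terms)
  terms <- c(terms, extraTerms)
  fml <- stats::as.formula(paste("logit_bc ~", paste(terms, collapse = " + "),
                                 "+ (1 | individual_id)"))
  fit <- lme4::lmer(fml, data = features, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: random-intercept variance is (numerically) zero")
  vc <- as.data.frame(lme4::VarCorr(fit))
  reVar <- vc$vcov[vc$grp == "individual_id"]
  resVar <- vc$vcov[vc$grp == "Residual"]
  cf <- summary(fit)$coefficients
  z <- cf[, "Estimate"] / cf[, "Std. Error"]
  fe <- data.frame(term = rownames(cf),
                   estimate = cf[, "Estimate"],
                   se = cf[, "Std. Error"],
                   z = z,
                   p = 2 * stats::pnorm(-abs(z)),
                   stringsAsFactors = FALSE)
  rownames(fe) <- NULL
  re <- lme4::ranef(fit)$individual_id
  ranef <- stats::setNames(re[["(Intercept)"]], rownames(re))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  eps <- attr(features, "clipEpsilon")
  new("AccuracyModelFit", fixedEffects = fe,
      randomInterceptVariance = as.numeric(reVar),
      residualVariance = as.numeric(resVar),
      converged = conv, singular = singular,
      ranef = ranef,
      clipEpsilon = if (is.null(eps)) 1e-3 else eps,
      terms = terms)
}

#' @rdname fixedEffects
#' @export
setMethod("fixedEffects", "AccuracyModelFit", function(object) object@fixedEffects)

setMethod("show", "AccuracyModelFit", function(object) {
  cat("AccuracyModelFit —", nrow(object@fixedEffects), "fixed effects,",
      length(object@ranef), "individuals\n")
  cat("  random-intercept variance:",
      format(object@randomInterceptVariance, digits = 4),
      if (object@singular) "(singular)", "\n")
  print(object@fixedEffects, digits = 4)
})

#' Wald tests of the fixed effects
#'
#' `z = estimate / se`, two-sided p from the normal approximation; an
#' exactly-zero standard error yields `NaN`.
#'
#' @param fit an [AccuracyModelFit-class].
#' @return data.frame with `term`, `z`, `p`.
#' @export
waldTests <- function(fit) {
  stopifnot(is(fit, "AccuracyModelFit"))
  fe <- fit@fixedEffects
  z <- ifelse(fe$se == 0, NaN, fe$estimate / fe$se)
  data.frame(term = fe$term, z = z,
             p = ifelse(is.nan(z), NaN, 2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' Predict interpolation accuracy for new feature rows
#'
#' Applies the fixed-effect linear predictor (plus the individual's fitted
#' intercept deviation when known and `includeRandom = TRUE`) and maps the
#' result back to the Bray-Curtis scale through the inverse logit. Unseen
#' individuals fall back to the fixed effects only and are flagged in the
#' `"unseen"` attribute.
#'
#' @param fit an [AccuracyModelFit-class].
#' @param features feature rows as from [buildAccuracyFeatures()].
#' @param includeRandom add known individual intercepts (default `TRUE`).
#' @return numeric vector of predicted Bray-Curtis similarities in
#'   `[0, 1]`.
#' @export
predictAccuracy <- function(fit, features, includeRandom = TRUE) {
  stopifnot(is(fit, "AccuracyModelFit"))
  if (!all(fit@terms %in% names(features)))
    stop("feature columns do not match the fitted covariates")
  fe <- stats::setNames(fit@fixedEffects$estimate, fit@fixedEffects$term)
  X <- cbind(1, as.matrix(features[, fit@terms, drop = FALSE]))
  eta <- drop(X %*% fe[c("(Intercept)", fit@terms)])
  unseen <- rep(FALSE, nrow(features))
  if (includeRandom) {
    hit <- match(features$individual_id, names(fit@ranef))
    unseen <- is.na(hit)
    eta <- eta + ifelse(unseen, 0, fit@ranef[hit])
  }
  out <- invLogit(eta)
  attr(out, "unseen") <- unseen
  out
}

#' Evaluate the accuracy predictor on held-out rows
#'
#' @param fit an [AccuracyModelFit-class].
#' @param features held-out feature rows (at least 10).
#' @param includeRandom passed to [predictAccuracy()]; held-out
#'   *individuals* are never seen, so their predictions use fixed effects
#'   only either way.
#' @return list with `mae` (mean absolute error on the Bray-Curtis scale)
#'   and `spearman` (rho between predicted and observed; `NaN` under zero
#'   variance).
#' @export
evaluatePredictor <- function(fit, features, includeRandom = FALSE) {
  stopifnot(nrow(features) >= 10L)
  pred <- predictAccuracy(fit, features, includeRandom = includeRandom)
  obs <- features$bc_similarity
  rho <- suppressWarnings(stats::cor(pred, obs, method = "spearman"))
  list(mae = mean(abs(pred - obs)),
       spearman = if (is.na(rho)) NaN else rho)
}
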