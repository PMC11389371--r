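#' Shannon diversity of a composition (nats)
#'
#' `-sum x_i ln x_i` over the positive entries; maximal (`ln n`) for the
#' uniform composition.
#'
#' @param x composition vector on the simplex.
#' @return diversity in nats.
#' @export
shannonDiversity <- function(x) {
  x <- x[x > 0]
  -sum(x * log(x))
}

#' Community stability around a time point
#'
#' The local stability of the community at interior sample `index` is the
#' mean of three Bray-Curtis similarities among the surrounding samples:
#' the two preceding samples compared with each other, the two succeeding
#' samples compared with each other, and the nearest preceding sample
#' compared with the nearest succeeding one. Requires two samples on each
#' side; otherwise returns `NaN` (flagged via the `"incomplete"` attribute).
#'
#' @param profile a [LongitudinalProfile-class].
#' @param index 1-based interior sample position.
#' @return stability in `[0, 1]`, or `NaN` when the context is incomplete.
#' @export
timepointStability <- function(profile, index) {
  stopifnot(is(profile, "LongitudinalProfile"))
  n <- nSamples(profile)
  if (index < 1L || index > n) stop("sample index out of range")
  if (index < 3L || index > n - 2L) {
    out <- NaN
    attr(out, "incomplete") <- TRUE
    return(out)
  }
  ab <- abundanceMatrix(profile)
  mean(c(brayCurtisSimilarity(ab[index - 2L, ], ab[index - 1L, ]),
         brayCurtisSimilarity(ab[index + 1L, ], ab[index + 2L, ]),
         brayCurtisSimilarity(ab[index - 1L, ], ab[index + 1L, ])))
}

#' Bimodality coefficient of an abundance series
#'
#' `beta = (gamma^2 + 1) / (kappa + 3 (n-1)^2 / ((n-2)(n-3)))` where
#' `gamma` is the sample skewness and `kappa` the sample *excess* kurtosis
#' (bias-uncorrected moment estimators; the finite-n correction term in the
#' denominator already plays that role). Benchmarks: a uniform sample gives
#' `beta -> 5/9`, a symmetric two-point mixture `beta -> 1`, a normal
#' sample `beta -> 1/3`. High values flag bimodal, conditionally-rare or
#' strongly fluctuating (non-stable) taxa.
#'
#' @param values numeric vector with at least 4 values and nonzero
#'   variance.
#' @return a list with `beta`, `skewness`, `kurtosis_excess`, `n`.
#' @export
bimodalityCoefficient <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4L) stop("bimodality coefficient needs at least 4 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0) stop("bimodality coefficient undefined for zero-variance data")
  g <- mean((values - m)^3) / m2^1.5
  k <- mean((values - m)^4) / m2^2 - 3
  beta <- (g^2 + 1) / (k + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  list(beta = beta, skewness = g, kurtosis_excess = k, n = n)
}

#' Classify a taxon as stable or non-stable from its bimodality
#'
#' Default orientation: a bimodality coefficient above the threshold marks
#' a *non-stable* taxon (conditionally rare or strongly fluctuating); the
#' comparison is strict, so `beta` equal to the threshold is stable. The
#' orientation can be flipped with `highIsStable = TRUE`.
#'
#' @param beta bimodality coefficient(s).
#' @param threshold classification threshold (default 0.7).
#' @param highIsStable flip the orientation.
#' @return character vector of `"stable"` / `"non_stable"`.
#' @export
classifyTaxonStability <- function(beta, threshold = 0.7, highIsStable = FALSE) {
  stopifnot(all(is.finite(beta)))
  high <- beta > threshold
  if (highIsStable) ifelse(high, "stable", "non_stable")
  else ifelse(high, "non_stable", "stable")
}

#' Per-taxon bimodality table for a set of profiles
#'
#' @param profiles list of [LongitudinalProfile-class] objects.
#' @param excludeOthers drop the `"others"` aggregate column from the table.
#' @param othersLabel label of the aggregate column.
#' @return data.frame with `individual_id`, `taxon`, `beta`,
#'   `mean_abundance`, `n`; taxa with zero variance in an individual are
#'   skipped.
#' @export
taxonBimodalityTable <- function(profiles, excludeOthers = FALSE,
                                 othersLabel = "others") {
  rows <- list()
  for (p in profiles) {
    ab <- abundanceMatrix(p)
    for (tx in colnames(ab)) {
      if (excludeOthers && tx == othersLabel) next
      v <- ab[, tx]
      if (length(v) < 4L || stats::sd(v) == 0) next
      bs <- bimodalityCoefficient(v)
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = individualId(p), taxon = tx, beta = bs$beta,
        mean_abundance = mean(v), n = bs$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Stability-accuracy correlation at the sample, taxon, or individual level
#'
#' * `sample`: Spearman correlation between [timepointStability()] at each
#'   leave-one-out target and its accuracy.
#' * `taxon`: contrast of per-taxon relative errors between stable and
#'   non-stable taxa (classified by [classifyTaxonStability()]); returns
#'   the two group means and a Wilcoxon p-value.
#' * `individual`: Spearman correlation between an individual's mean taxon
#'   bimodality and its mean accuracy.
#'
#' @param evals list of [LooEvaluation-class] objects (same method), one
#'   per individual.
#' @param profiles matching list of [LongitudinalProfile-class] objects
#'   (full profiles the evaluations were run on).
#' @param level `"sample"`, `"taxon"`, or `"individual"`.
#' @param threshold bimodality classification threshold for the taxon level.
#' @return a list; for the Spearman levels `rho`, `p`, `n`, for the taxon
#'   level `mean_relative_error_stable`, `mean_relative_error_non_stable`,
#'   `p`, `n`.
#' @export
stabilityAccuracyCorrelation <- function(evals, profiles,
                                         level = c("sample", "taxon", "individual"),
                                         threshold = 0.7) {
  level <- match.arg(level)
  stopifnot(length(evals) == length(profiles))
  if (level == "sample") {
    st <- numeric(0); acc <- numeric(0)
    for (k in seq_along(evals)) {
      r <- records(evals[[k]])
      s <- vapply(r$target_index, function(i)
        suppressWarnings(as.numeric(timepointStability(profiles[[k]], i))),
        numeric(1))
      ok <- !r$failed & is.finite(s) & !is.na(r$bc_similarity)
      st <- c(st, s[ok]); acc <- c(acc, r$bc_similarity[ok])
    }
    if (length(st) < 5L) return(list(rho = NaN, p = NaN, n = length(st)))
    out <- spearmanWithP(st, acc)
    return(list(rho = out[["rho"]], p = out[["p"]], n = out[["n"]]))
  }
  bim <- taxonBimodalityTable(profiles)
  if (level == "individual") {
    meanBeta <- tapply(bim$beta, bim$individual_id, mean)
    meanAcc <- vapply(evals, function(e) {
      r <- records(e); mean(r$bc_similarity[!r$failed], na.rm = TRUE)
    }, numeric(1))
    names(meanAcc) <- vapply(evals, function(e) records(e)$individual_id[1L], "")
    ids <- intersect(names(meanBeta), names(meanAcc))
    if (length(ids) < 5L) return(list(rho = NaN, p = NaN, n = length(ids)))
    out <- spearmanWithP(as.numeric(meanBeta[ids]), as.numeric(meanAcc[ids]))
    return(list(rho = out[["rho"]], p = out[["p"]], n = out[["n"]]))
  }
  # taxon level: relative error split by stability class
  errStable <- numeric(0); errNon <- numeric(0)
  for (k in seq_along(evals)) {
    e <- evals[[k]]
    id <- records(e)$individual_id[1L]
    b <- bim[bim$individual_id == id, , drop = FALSE]
    if (!nrow(b)) next
    cls <- classifyTaxonStability(b$beta, threshold = threshold)
    re <- relativeErrors(e)
    meanErr <- suppressWarnings(
      vapply(b$taxon, function(tx) mean(re[, tx], na.rm = TRUE), numeric(1)))
    errStable <- c(errStable, meanErr[cls == "stable" & is.finite(meanErr)])
    errNon <- c(errNon, meanErr[cls == "non_stable" & is.finite(meanErr)])
  }
  p <- if (length(errStable) >= 2L && length(errNon) >= 2L)
    suppressWarnings(stats::wilcox.test(errNon, errStable,
                                        alternative = "greater")$p.value)
  else NaN
  list(mean_relative_error_stable = mean(errStable),
       mean_relative_error_non_stable = mean(errNon),
       p = p, n = length(errStable) + length(errNon))
}

#' Spearman correlation between taxon bimodality and mean abundance
#'
#' Across all (taxon, individual) pairs: do rarer taxa fluctuate more?
#'
#' @param profiles list of [LongitudinalProfile-class] objects contributing
#'   at least 10 (taxon, individual) pairs.
#' @return list with `rho`, `p`, `n`.
#' @export
bimodalityAbundanceCorrelation <- function(profiles) {
  bim <- taxonBimodalityTable(profiles)
  if (is.null(bim) || nrow(bim) < 10L)
    stop("need at least 10 (taxon, individual) pairs")
  out <- spearmanWithP(bim$beta, bim$mean_abundance)
  list(rho = out[["rho"]], p = out[["p"]], n = out[["n"]])
}
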