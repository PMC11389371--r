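# Cross-record correlation analyses: where does interpolation accuracy
# covary — in time, within individuals, within cohorts?

pearsonWithP <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NaN, p = NaN, n = length(x)))
  ct <- stats::cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

spearmanWithP <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(rho = NaN, p = NaN, n = length(x)))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  c(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Temporal autocorrelation of interpolation accuracy
#'
#' Bins all record pairs of one individual/method by the absolute time lag
#' between their targets and reports, per lag bin, the Pearson correlation
#' between the paired accuracy values.
#'
#' @param recs records of a single individual and method (data.frame or
#'   [LooEvaluation-class]) with at least 10 non-failed records.
#' @param lagBins vector of lag bin edges in days (passed to [cut()]).
#' @return data.frame with `bin`, `n_pairs`, `r`; bins with fewer than 3
#'   pairs give `NaN`.
#' @export
accuracyAutocorrelation <- function(recs, lagBins) {
  if (is(recs, "LooEvaluation")) recs <- records(recs)
  recs <- recs[!recs$failed & !is.na(recs$bc_similarity), , drop = FALSE]
  if (nrow(recs) < 10L) stop("need at least 10 records")
  pairs <- utils::combn(nrow(recs), 2L)
  lag <- abs(recs$target_time[pairs[1L, ]] - recs$target_time[pairs[2L, ]])
  a <- recs$bc_similarity[pairs[1L, ]]
  b <- recs$bc_similarity[pairs[2L, ]]
  binned <- cut(lag, breaks = lagBins, include.lowest = TRUE)
  out <- data.frame(bin = levels(binned), n_pairs = 0L, r = NaN)
  for (k in seq_along(levels(binned))) {
    sel <- which(binned == levels(binned)[k])
    out$n_pairs[k] <- length(sel)
    if (length(sel) >= 3L) {
      # symmetrize so the pair ordering is immaterial
      r <- suppressWarnings(stats::cor(c(a[sel], b[sel]), c(b[sel], a[sel])))
      out$r[k] <- if (is.na(r)) NaN else r
    }
  }
  out
}

#' Accuracy correlation with neighbouring / random context
#'
#' For every record, pairs its accuracy with (a) the mean accuracy of the
#' temporally adjacent records of the same individual (one-sided at
#' boundaries), (b) a random record of the same individual, (c) a random
#' record of the same dataset (other individuals included), and (d) a
#' random record of a different dataset; reports the Pearson r of each
#' pairing per method. Random pairings are drawn `nDraws` times and the
#' resulting coefficients averaged.
#'
#' @param recs combined records across individuals and datasets (see
#'   [combineRecords()]).
#' @param seed integer seed for the random pairings.
#' @param nDraws number of random-pairing draws to average over.
#' @return data.frame with columns `method`, `context`, `r`, `n`; a context
#'   that does not exist (e.g. a single dataset for `other_dataset`) gives
#'   `NaN`.
#' @export
neighborContextCorrelation <- function(recs, seed = 1L, nDraws = 1L) {
  recs <- recs[!recs$failed & !is.na(recs$bc_similarity), , drop = FALSE]
  set.seed(seed)
  out <- list()
  for (m in unique(recs$method)) {
    d <- recs[recs$method == m, , drop = FALSE]
    d <- d[order(d$individual_id, d$target_time), , drop = FALSE]
    acc <- d$bc_similarity
    ind <- d$individual_id
    ds <- d$dataset
    nrec <- nrow(d)
    adj <- vapply(seq_len(nrec), function(i) {
      same <- which(ind == ind[i])
      pos <- match(i, same)
      nb <- same[c(pos - 1L, pos + 1L)]
      nb <- nb[!is.na(nb)]
      if (!length(nb)) NaN else mean(acc[nb])
    }, numeric(1))
    randMean <- function(poolFun) {
      rs <- vapply(seq_len(nDraws), function(draw) {
        partner <- vapply(seq_len(nrec), function(i) {
          pool <- poolFun(i)
          if (!length(pool)) return(NaN)
          acc[pool[sample.int(length(pool), 1L)]]
        }, numeric(1))
        pearsonWithP(acc, partner)[["r"]]
      }, numeric(1))
      mean(rs)
    }
    vals <- c(
      adjacent = pearsonWithP(acc, adj)[["r"]],
      same_individual = randMean(function(i) setdiff(which(ind == ind[i]), i)),
      same_dataset = randMean(function(i)
        setdiff(which(ds == ds[i] & !is.na(ds)), i)),
      other_dataset = randMean(function(i)
        which(ds != ds[i] & !is.na(ds) & !is.na(ds[i]))))
    out[[m]] <- data.frame(method = m, context = names(vals), r = unname(vals),
                           n = nrec, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Correlation between Shannon diversity and interpolation accuracy
#'
#' Per individual, the Pearson correlation between the Shannon diversity of
#' each held-out true sample and the accuracy with which it was
#' interpolated.
#'
#' @param evals list of [LooEvaluation-class] objects (one per individual,
#'   same method).
#' @return data.frame with `individual_id`, `r`, `p`, `n`; individuals with
#'   fewer than 5 usable records or zero variance give `NaN`.
#' @export
diversityAccuracyCorrelation <- function(evals) {
  out <- lapply(evals, function(e) {
    stopifnot(is(e, "LooEvaluation"))
    r <- records(e)
    ok <- !r$failed & !is.na(r$bc_similarity)
    div <- apply(e@actual, 1L, shannonDiversity)
    stats <- if (sum(ok) >= 5L) pearsonWithP(div[ok], r$bc_similarity[ok])
             else c(r = NaN, p = NaN, n = sum(ok))
    data.frame(individual_id = r$individual_id[1L],
               r = stats[["r"]], p = stats[["p"]], n = as.integer(stats[["n"]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Between-method agreement of per-individual accuracy
#'
#' Pairwise Pearson correlation matrix of the per-individual mean
#' accuracies of each method (pairwise-complete when a method is missing an
#' individual).
#'
#' @param recs combined records across methods and at least 3 individuals.
#' @return symmetric correlation matrix with unit diagonal, methods as
#'   dimnames.
#' @export
methodAgreement <- function(recs) {
  s <- summarizeAccuracy(recs, groupBy = c("method", "individual_id"))
  wide <- stats::reshape(s[, c("method", "individual_id", "mean_bc")],
                         direction = "wide", idvar = "individual_id",
                         timevar = "method")
  m <- as.matrix(wide[, -1L, drop = FALSE])
  colnames(m) <- sub("^mean_bc\\.", "", colnames(m))
  if (nrow(m) < 3L) stop("method agreement needs at least 3 individuals")
  if (anyNA(m))
    warning("method(s) missing individuals; using pairwise-complete correlations")
  cc <- stats::cor(m, use = "pairwise.complete.obs")
  diag(cc) <- 1
  cc
}
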