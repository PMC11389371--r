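#' Bray-Curtis similarity between two compositions
#'
#' `1 - sum|x_i - y_i| / sum(x_i + y_i)`. For two simplex vectors this
#' equals `sum min(x_i, y_i)`. Values lie in `[0, 1]`, 1 meaning identical
#' compositions.
#'
#' @param x,y non-negative abundance vectors over the same taxa.
#' @return similarity in `[0, 1]`.
#' @examples
#' brayCurtisSimilarity(c(0.5, 0.5, 0), c(1, 0, 0))  # 0.5
#' @export
brayCurtisSimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("compositions must be aligned")
  tot <- sum(x + y)
  if (tot <= 0) stop("both compositions are all-zero")
  1 - sum(abs(x - y)) / tot
}

#' Per-taxon relative interpolation error
#'
#' `|real_i - predicted_i| / real_i`, with `NaN` where the true abundance is
#' zero (those entries are excluded from aggregates). The log relative
#' error used for reporting is the natural log of the positive entries.
#'
#' @param real true composition.
#' @param predicted interpolated composition.
#' @return numeric vector of relative errors (NaN at zero-truth taxa).
#' @export
relativeError <- function(real, predicted) {
  if (length(real) != length(predicted)) stop("compositions must be aligned")
  out <- abs(real - predicted) / real
  out[real == 0] <- NaN
  out
}

#' Leave-one-out evaluation of one interpolation method
#'
#' For every interior sample of the profile (the first and last samples are
#' never targets, so every prediction is an interpolation): remove it,
#' refit any trainable method on the remaining samples, predict the
#' composition at the omitted time, and score the prediction with
#' Bray-Curtis similarity and per-taxon relative errors. A method failure
#' at a target is recorded as a flagged row (NA scores), never silently
#' dropped.
#'
#' @param profile a [LongitudinalProfile-class] with at least 3 samples.
#' @param method a method name from [interpolationMethods()].
#' @param params named list of method parameters (see [interpolateAt()]).
#' @param seed optional seed forwarded to stochastic estimators (LIMITS);
#'   a per-target sub-seed is derived so records are independent of
#'   evaluation order.
#' @return a [LooEvaluation-class] with `nSamples(profile) - 2` records in
#'   time order.
#' @export
looEvaluate <- function(profile, method, params = list(), seed = NULL) {
  stopifnot(is(profile, "LongitudinalProfile"))
  n <- nSamples(profile)
  if (n < 3L) stop("leave-one-out evaluation needs at least 3 samples")
  method <- match.arg(method, interpolationMethods())
  tms <- sampleTimes(profile)
  ab <- abundanceMatrix(profile)
  idx <- seq(2L, n - 1L)
  nt <- nTaxa(profile)
  pred <- matrix(NA_real_, length(idx), nt, dimnames = list(NULL, taxa(profile)))
  relerr <- pred
  bc <- rep(NA_real_, length(idx))
  failed <- logical(length(idx))
  msg <- character(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    sub <- dropSample(profile, i)
    subSeed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    res <- tryCatch(
      interpolateAt(sub, tms[i], method, params = params, seed = subSeed),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[k] <- TRUE
      msg[k] <- conditionMessage(res)
    } else {
      pred[k, ] <- res
      bc[k] <- brayCurtisSimilarity(ab[i, ], res)
      relerr[k, ] <- relativeError(ab[i, ], res)
    }
  }
  recs <- data.frame(
    individual_id = individualId(profile),
    dataset = datasetLabel(profile),
    method = method,
    target_index = idx,
    target_time = tms[idx],
    bc_similarity = bc,
    gap_prev = tms[idx] - tms[idx - 1L],
    gap_next = tms[idx + 1L] - tms[idx],
    n_samples_available = n - 1L,
    failed = failed,
    message = msg,
    stringsAsFactors = FALSE)
  new("LooEvaluation", records = recs, predicted = pred,
      actual = ab[idx, , drop = FALSE], relativeErrors = relerr,
      taxa = taxa(profile))
}

#' @rdname records
#' @export
setMethod("records", "LooEvaluation", function(object) object@records)

#' @rdname relativeErrors
#' @export
setMethod("relativeErrors", "LooEvaluation", function(object) object@relativeErrors)

setMethod("show", "LooEvaluation", function(object) {
  r <- object@records
  cat("LooEvaluation:", r$method[1L], "on", r$individual_id[1L], "—",
      nrow(r), "targets\n")
  ok <- !r$failed
  cat("  mean Bray-Curtis similarity:",
      format(mean(r$bc_similarity[ok]), digits = 4),
      if (any(!ok)) paste0("(", sum(!ok), " failed)"), "\n")
})

#' Combine the record tables of several evaluations
#'
#' @param evals list of [LooEvaluation-class] objects (or record
#'   data.frames).
#' @return a single tidy data.frame, one row per (method, target).
#' @export
combineRecords <- function(evals) {
  dfs <- lapply(evals, function(e) if (is(e, "LooEvaluation")) records(e) else e)
  do.call(rbind, c(dfs, list(make.row.names = FALSE)))
}

#' Summarize interpolation accuracy by group
#'
#' Grouped means/medians of the Bray-Curtis similarity with record counts;
#' failed records are excluded from the scores but counted. Within each
#' grouping stratum other than method, methods are ranked by mean
#' similarity (rank 1 = most accurate).
#'
#' @param recs a record data.frame (see [combineRecords()]) or a
#'   [LooEvaluation-class].
#' @param groupBy columns to group by: subset of
#'   `c("method", "individual_id", "dataset")`.
#' @return a data.frame of group summaries.
#' @export
summarizeAccuracy <- function(recs, groupBy = c("method", "individual_id")) {
  if (is(recs, "LooEvaluation")) recs <- records(recs)
  stopifnot(nrow(recs) > 0)
  groupBy <- match.arg(groupBy, c("method", "individual_id", "dataset"),
                       several.ok = TRUE)
  key <- interaction(recs[groupBy], drop = TRUE, lex.order = TRUE)
  parts <- split(recs, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    ok <- !d$failed & !is.na(d$bc_similarity)
    cbind(d[1L, groupBy, drop = FALSE],
          data.frame(n = nrow(d), n_failed = sum(!ok),
                     mean_bc = if (any(ok)) mean(d$bc_similarity[ok]) else NA_real_,
                     median_bc = if (any(ok)) stats::median(d$bc_similarity[ok]) else NA_real_))
  }))
  rownames(out) <- NULL
  if ("method" %in% groupBy && length(groupBy) > 1L) {
    strat <- interaction(out[setdiff(groupBy, "method")], drop = TRUE)
    out$rank <- stats::ave(-out$mean_bc, strat,
                           FUN = function(v) rank(v, ties.method = "min"))
  } else if (identical(groupBy, "method")) {
    out$rank <- rank(-out$mean_bc, ties.method = "min")
  }
  out
}

#' Monte-Carlo subsampling experiment (sample size / sampling frequency)
#'
#' Emulates sparser studies by subsampling each profile: for every
#' requested size and replicate, the two endpoint samples are always
#' retained (so every target is an interpolation problem), the remaining
#' samples are drawn uniformly without replacement, one random interior
#' retained sample is chosen as the target, and the method interpolates it
#' from the rest. Seeded and reproducible.
#'
#' @param profile a [LongitudinalProfile-class].
#' @param method,params as in [interpolateAt()].
#' @param sizes integer vector of subsample sizes (each at least 3). Sizes
#'   exceeding `nSamples(profile)` are skipped with a warning.
#' @param replicates replicates per size.
#' @param seed integer seed.
#' @return a data.frame with one row per (size, replicate):
#'   `individual_id`, `sample_size`, `replicate`, `seed`, `target_time`,
#'   `gap_prev`, `bc_similarity`, `failed`.
#' @export
subsampleExperiment <- function(profile, method, sizes, replicates = 10,
                                params = list(), seed = 1L) {
  stopifnot(is(profile, "LongitudinalProfile"), all(sizes >= 3))
  n <- nSamples(profile)
  bad <- sizes > n
  if (any(bad)) {
    warning("skipping size(s) exceeding the ", n, " available samples: ",
            paste(sizes[bad], collapse = ", "))
    sizes <- sizes[!bad]
  }
  tms <- sampleTimes(profile)
  ab <- abundanceMatrix(profile)
  rows <- list()
  for (size in sizes) {
    for (rep in seq_len(replicates)) {
      repSeed <- (seed + 7919L * size + rep) %% .Machine$integer.max
      set.seed(repSeed)
      resample <- function(x, k) x[sample.int(length(x), k)]
      interior <- resample(setdiff(seq_len(n), c(1L, n)), size - 2L)
      keep <- sort(c(1L, interior, n))
      targetPos <- resample(seq(2L, size - 1L), 1L)
      target <- keep[targetPos]
      rest <- subsetSamples(profile, setdiff(keep, target))
      res <- tryCatch(
        interpolateAt(rest, tms[target], method, params = params,
                      seed = repSeed),
        error = function(e) e)
      failedRun <- inherits(res, "error")
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = individualId(profile),
        method = method,
        sample_size = size,
        replicate = rep,
        seed = repSeed,
        target_time = tms[target],
        gap_prev = tms[target] - tms[keep[targetPos - 1L]],
        bc_similarity = if (failedRun) NA_real_ else
          brayCurtisSimilarity(ab[target, ], res),
        failed = failedRun,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Stratified means: accuracy vs one factor with the other held fixed
#'
#' Disentangles sample size from sampling frequency: holds `fix`
#' (`"sample_size"` or `"gap_prev"`) within strata and reports the mean
#' accuracy across bins of the free variable inside each stratum.
#'
#' @param results a data.frame from [subsampleExperiment()] (rows from
#'   several profiles may be concatenated).
#' @param fix which variable to hold fixed.
#' @param bins for a continuous free/fixed variable, either a bin count or
#'   a vector of break points (passed to [cut()]).
#' @return a data.frame with columns `stratum`, `bin`, `mean_bc`, `n`;
#'   empty strata yield `NaN` rows.
#' @export
stratifiedEffects <- function(results, fix = c("sample_size", "gap_prev"),
                              bins = 3) {
  fix <- match.arg(fix)
  stopifnot(nrow(results) > 0)
  free <- setdiff(c("sample_size", "gap_prev"), fix)
  results <- results[!results$failed & !is.na(results$bc_similarity), , drop = FALSE]
  strat <- if (fix == "sample_size") factor(results$sample_size)
           else cut(results$gap_prev, breaks = bins, include.lowest = TRUE)
  binv <- if (free == "sample_size") factor(results$sample_size)
          else cut(results$gap_prev, breaks = bins, include.lowest = TRUE)
  agg <- expand.grid(stratum = levels(strat), bin = levels(binv),
                     stringsAsFactors = FALSE)
  agg$mean_bc <- NaN
  agg$n <- 0L
  for (r in seq_len(nrow(agg))) {
    sel <- strat == agg$stratum[r] & binv == agg$bin[r]
    agg$n[r] <- sum(sel)
    if (agg$n[r] > 0) agg$mean_bc[r] <- mean(results$bc_similarity[sel])
  }
  agg
}
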