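#' Construct a longitudinal profile
#'
#' Builds a [LongitudinalProfile-class] from a samples-by-taxa abundance
#' matrix and its sampling days. Rows may be counts or proportions; each row
#' is renormalized to the simplex. Rows are reordered by time and times are
#' shifted so the first sample is day 0.
#'
#' @param abundances numeric matrix `[n_samples x n_taxa]`, non-negative,
#'   with taxon names as column names; counts or proportions.
#' @param times numeric vector of sampling days, one per row; duplicates are
#'   rejected.
#' @param individualId single character label.
#' @param dataset optional cohort/study label (used to group individuals in
#'   cross-individual analyses).
#' @return a validated `LongitudinalProfile`.
#' @examples
#' m <- rbind(c(3, 1), c(1, 1), c(1, 3))
#' colnames(m) <- c("A", "B")
#' p <- LongitudinalProfile(m, times = c(0, 2, 5), individualId = "ind1")
#' abundanceMatrix(p)
#' @export
LongitudinalProfile <- function(abundances, times, individualId,
                                dataset = NA_character_) {
  abundances <- as.matrix(abundances)
  if (is.null(colnames(abundances)))
    colnames(abundances) <- paste0("taxon_", seq_len(ncol(abundances)))
  if (length(times) != nrow(abundances))
    stop("need one time stamp per sample row")
  if (anyDuplicated(times))
    stop("duplicate sampling times: ", paste(times[duplicated(times)], collapse = ", "))
  if (any(!is.finite(times)))
    stop("times must be finite")
  if (any(abundances < 0))
    stop("abundances must be non-negative")
  rs <- rowSums(abundances)
  if (any(rs <= 0))
    stop("all-zero sample row(s): ", paste(which(rs <= 0), collapse = ", "))
  ord <- order(times)
  abundances <- abundances[ord, , drop = FALSE] / rs[ord]
  times <- times[ord] - times[ord][1L]
  rownames(abundances) <- NULL
  new("LongitudinalProfile",
      individualId = as.character(individualId),
      dataset = as.character(dataset),
      times = as.numeric(times),
      abundances = abundances)
}

#' @rdname LongitudinalProfile-class
#' @export
setMethod("individualId", "LongitudinalProfile", function(object) object@individualId)

#' @rdname LongitudinalProfile-class
#' @export
setMethod("datasetLabel", "LongitudinalProfile", function(object) object@dataset)

#' @rdname LongitudinalProfile-class
#' @export
setMethod("sampleTimes", "LongitudinalProfile", function(object) object@times)

#' @rdname LongitudinalProfile-class
#' @export
setMethod("abundanceMatrix", "LongitudinalProfile", function(object) object@abundances)

#' @rdname LongitudinalProfile-class
#' @export
setMethod("taxa", "LongitudinalProfile", function(object) colnames(object@abundances))

#' @rdname LongitudinalProfile-class
#' @export
setMethod("nSamples", "LongitudinalProfile", function(object) nrow(object@abundances))

#' @rdname LongitudinalProfile-class
#' @export
setMethod("nTaxa", "LongitudinalProfile", function(object) ncol(object@abundances))

setMethod("show", "LongitudinalProfile", function(object) {
  cat("LongitudinalProfile:", object@individualId,
      if (!is.na(object@dataset)) paste0("(", object@dataset, ")"), "\n")
  cat(" ", nSamples(object), "samples over",
      format(max(object@times), digits = 4), "days;",
      nTaxa(object), "taxa\n")
  cat("  mean interval:",
      format(mean(diff(object@times)), digits = 4), "days\n")
})

#' Drop one sample from a profile
#'
#' Utility used by the leave-one-out machinery: returns the profile without
#' the sample at `index`. Times are kept on the original day scale (the
#' first sample is always retained, so day 0 is unchanged when removing
#' interior samples).
#'
#' @param profile a [LongitudinalProfile-class].
#' @param index 1-based sample index to remove.
#' @return a `LongitudinalProfile` with `nSamples(profile) - 1` rows.
#' @export
dropSample <- function(profile, index) {
  stopifnot(is(profile, "LongitudinalProfile"))
  n <- nSamples(profile)
  if (index < 1L || index > n) stop("sample index out of range")
  if (n <= 2L) stop("cannot drop a sample from a 2-sample profile")
  keep <- setdiff(seq_len(n), index)
  new("LongitudinalProfile",
      individualId = profile@individualId,
      dataset = profile@dataset,
      times = profile@times[keep],
      abundances = profile@abundances[keep, , drop = FALSE])
}

#' Restrict a profile to a subset of its samples
#'
#' @param profile a [LongitudinalProfile-class].
#' @param indices sorted 1-based sample indices to keep (at least 2).
#' @return a `LongitudinalProfile` over the kept samples.
#' @export
subsetSamples <- function(profile, indices) {
  stopifnot(is(profile, "LongitudinalProfile"))
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 2L) stop("need at least 2 samples")
  if (any(indices < 1L) || any(indices > nSamples(profile)))
    stop("sample indices out of range")
  new("LongitudinalProfile",
      individualId = profile@individualId,
      dataset = profile@dataset,
      times = profile@times[indices],
      abundances = profile@abundances[indices, , drop = FALSE])
}

#' Normalize a non-negative vector to the simplex
#'
#' @param values non-negative numeric vector with at least one positive
#'   entry.
#' @return `values / sum(values)`; names are preserved.
#' @examples
#' normalizeComposition(c(2, 2))
#' @export
normalizeComposition <- function(values) {
  if (any(values < 0)) stop("composition entries must be non-negative")
  s <- sum(values)
  if (!is.finite(s) || s <= 0)
    stop("cannot normalize an all-zero (or non-finite) composition")
  values / s
}

#' Keep the most abundant taxa and aggregate the rest as "others"
#'
#' Retains the `k` taxa with the highest mean relative abundance across the
#' individual's samples and sums all remaining taxa into a final `"others"`
#' column. The `"others"` column is always present (zero-valued when
#' `k >= nTaxa(profile)`), so every downstream method sees a fixed taxon
#' set. Ties in mean abundance at the k-th rank are broken by taxon label
#' (lexicographic), making the output deterministic.
#'
#' @param profile a [LongitudinalProfile-class].
#' @param k number of taxa to keep (default 30).
#' @param othersLabel label for the aggregate column.
#' @return a `LongitudinalProfile` with `min(k, nTaxa) + 1` columns whose
#'   rows still sum to one.
#' @export
selectTopTaxa <- function(profile, k = 30, othersLabel = "others") {
  stopifnot(is(profile, "LongitudinalProfile"), k >= 1)
  ab <- abundanceMatrix(profile)
  labels <- colnames(ab)
  # a previous aggregate column never competes with real taxa
  prior <- labels == othersLabel
  means <- colMeans(ab)
  ord <- order(-means, labels)
  ord <- ord[!prior[ord]]
  keep <- ord[seq_len(min(k, length(ord)))]
  keep <- keep[order(keep)]   # preserve original column order among kept
  others <- rowSums(ab[, setdiff(seq_along(labels), keep), drop = FALSE])
  out <- cbind(ab[, keep, drop = FALSE], others)
  colnames(out) <- c(labels[keep], othersLabel)
  new("LongitudinalProfile",
      individualId = profile@individualId,
      dataset = profile@dataset,
      times = profile@times,
      abundances = out / rowSums(out))
}
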