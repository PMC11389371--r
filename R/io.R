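#' Read a longitudinal profile from a delimited feature table
#'
#' Reads a taxa-by-samples (or samples-by-taxa) feature table plus a
#' two-column metadata table mapping sample ids to sampling days, and
#' assembles a [LongitudinalProfile-class]. Values may be raw counts or
#' proportions; each sample is renormalized on load.
#'
#' @param tablePath path to a tab- or comma-delimited feature table with a
#'   header row of ids and a first column of ids.
#' @param metadata either a path to a delimited two-column table
#'   (`sample_id`, `day`) or a data.frame with those columns.
#' @param individualId label for the individual.
#' @param orientation `"taxa_by_samples"` (default), `"samples_by_taxa"`, or
#'   `"auto"`, which matches the table's column names against the metadata
#'   sample ids.
#' @param dataset optional cohort label.
#' @param sep field separator; inferred from the file extension by default
#'   (`.csv` comma, otherwise tab).
#' @return a `LongitudinalProfile` with rows sorted by time.
#' @export
readProfile <- function(tablePath, metadata, individualId,
                        orientation = c("taxa_by_samples", "samples_by_taxa", "auto"),
                        dataset = NA_character_, sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", tablePath, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(tablePath, header = TRUE, sep = sep,
                           row.names = 1, check.names = FALSE,
                           comment.char = "", quote = "\"")
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("feature table must be numeric")
  if (is.data.frame(metadata)) {
    meta <- metadata
  } else {
    msep <- if (grepl("\\.csv$", metadata, ignore.case = TRUE)) "," else "\t"
    meta <- utils::read.table(metadata, header = TRUE, sep = msep,
                              check.names = FALSE, comment.char = "")
  }
  if (ncol(meta) < 2L)
    stop("metadata must have two columns: sample_id and day")
  ids <- as.character(meta[[1L]])
  days <- as.numeric(meta[[2L]])
  if (anyNA(days)) stop("missing/non-numeric day in metadata")
  names(days) <- ids

  if (orientation == "auto") {
    orientation <- if (mean(colnames(m) %in% ids) >= mean(rownames(m) %in% ids))
      "taxa_by_samples" else "samples_by_taxa"
  }
  if (orientation == "taxa_by_samples") m <- t(m)
  # now samples x taxa
  missing <- setdiff(rownames(m), ids)
  if (length(missing))
    stop("sample(s) without a time stamp: ", paste(missing, collapse = ", "))
  times <- days[rownames(m)]
  LongitudinalProfile(m, times = times, individualId = individualId,
                      dataset = dataset)
}

#' Read a longitudinal profile from a BIOM file
#'
#' Thin wrapper over the `biomformat` package (required only for this
#' function). The BIOM observation matrix is read as taxa-by-samples.
#'
#' @inheritParams readProfile
#' @param biomPath path to a BIOM file.
#' @export
readProfileBiom <- function(biomPath, metadata, individualId,
                            dataset = NA_character_) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("readProfileBiom() requires the 'biomformat' package")
  b <- biomformat::read_biom(biomPath)
  m <- as.matrix(biomformat::biom_data(b))   # taxa x samples
  if (is.data.frame(metadata)) meta <- metadata else
    meta <- utils::read.table(metadata, header = TRUE, sep = "\t",
                              check.names = FALSE)
  days <- as.numeric(meta[[2L]]); names(days) <- as.character(meta[[1L]])
  missing <- setdiff(colnames(m), names(days))
  if (length(missing))
    stop("sample(s) without a time stamp: ", paste(missing, collapse = ", "))
  LongitudinalProfile(t(m), times = days[colnames(m)],
                      individualId = individualId, dataset = dataset)
}

#' Write a profile (and its metadata) to delimited text
#'
#' Emits a taxa-by-samples table at full double precision plus a matching
#' `sample_id` / `day` metadata table, the inverse of [readProfile()].
#'
#' @param profile a [LongitudinalProfile-class].
#' @param tablePath output path for the feature table.
#' @param metadataPath optional output path for the metadata table.
#' @param sep field separator (default tab).
#' @return `tablePath`, invisibly.
#' @export
writeProfile <- function(profile, tablePath, metadataPath = NULL, sep = "\t") {
  stopifnot(is(profile, "LongitudinalProfile"))
  m <- t(abundanceMatrix(profile))   # taxa x samples
  ids <- paste0("S", formatC(seq_len(ncol(m)), width = 4, flag = "0"))
  colnames(m) <- ids
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     tablePath, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadataPath)) {
    meta <- data.frame(sample_id = ids,
                       day = format(sampleTimes(profile), digits = 17,
                                    scientific = FALSE, trim = TRUE))
    utils::write.table(meta, metadataPath, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(tablePath)
}
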