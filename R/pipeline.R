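#' Default pipeline configuration
#'
#' Settings for [runPipeline()]: which profiles to analyse (either paths to
#' delimited tables or a synthetic-cohort configuration), the method roster
#' with parameters, and the experiment toggles.
#'
#' @param input either `NULL` (simulate the cohort of `synthetic`) or a
#'   data.frame with columns `table`, `metadata`, `individual_id` and
#'   optionally `dataset` naming delimited input files.
#' @param synthetic a [syntheticConfig()] list used when `input` is `NULL`.
#' @param methods method names to evaluate (subset of
#'   [interpolationMethods()]).
#' @param params named list of per-method parameter lists, e.g.
#'   `list(knn = list(K = 5))`.
#' @param kTopTaxa top-taxa preprocessing cutoff (applied to file inputs;
#'   the synthetic generator already emits a fixed taxon set).
#' @param subsampleSizes sizes for the Monte-Carlo subsampling experiment
#'   (`NULL` disables it).
#' @param subsampleReplicates replicates per size.
#' @param accuracyModel fit the mixed-effects accuracy predictor per method.
#' @param seed integer master seed.
#' @return named configuration list.
#' @export
pipelineConfig <- function(input = NULL, synthetic = syntheticConfig(),
                           methods = c("mean", "median", "last", "equal",
                                       "weighted_average", "knn", "spline"),
                           params = list(),
                           kTopTaxa = 30,
                           subsampleSizes = NULL,
                           subsampleReplicates = 10,
                           accuracyModel = FALSE,
                           seed = 1L) {
  bad <- setdiff(methods, interpolationMethods())
  if (length(bad))
    stop("unknown interpolation method(s): ", paste(bad, collapse = ", "))
  list(input = input, synthetic = synthetic, methods = methods,
       params = params, kTopTaxa = kTopTaxa,
       subsampleSizes = subsampleSizes,
       subsampleReplicates = subsampleReplicates,
       accuracyModel = accuracyModel, seed = seed)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the full study on a set of profiles: preprocessing,
#' leave-one-out evaluation of every configured method, accuracy summaries,
#' per-sample stability and per-taxon bimodality tables, the optional
#' Monte-Carlo subsampling experiment, and the optional accuracy-prediction
#' model. All outputs are delimited text tables in `outDir`, plus a JSON
#' manifest recording the configuration, seed, and package version. A
#' method that fails on a profile is recorded and skipped, never aborting
#' the run. Given identical seeds, reruns are byte-identical.
#'
#' @param config a list from [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @return `outDir`, invisibly; side effect: `records.tsv`,
#'   `summary_method.tsv`, `summary_individual.tsv`, `stability.tsv`,
#'   `bimodality.tsv`, optional `subsample.tsv`, optional
#'   `accuracy_model_<method>.tsv` + predictions, `manifest.json`, and a
#'   plain-text `pipeline.log`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  stopifnot(is.list(config), !missing(outDir))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "pipeline.log")
  logLines <- character(0)
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    logLines <<- c(logLines, line)
    message(line)
  }
  writeTable <- function(df, name, digits = 15) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                   format = "g"))
    utils::write.table(df, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # ---- load or simulate profiles ----
  if (is.null(config$input)) {
    note("simulating synthetic cohort (seed ", config$synthetic$seed, ")")
    cohort <- simulateCohort(config$synthetic)
    profiles <- cohort$profiles
  } else {
    note("reading ", nrow(config$input), " input profile(s)")
    profiles <- list()
    for (r in seq_len(nrow(config$input))) {
      row <- config$input[r, ]
      ds <- if ("dataset" %in% names(row)) row$dataset else NA_character_
      p <- readProfile(row$table, row$metadata, row$individual_id, dataset = ds)
      profiles[[row$individual_id]] <- selectTopTaxa(p, k = config$kTopTaxa)
    }
  }

  # ---- leave-one-out evaluation ----
  evals <- list()
  allRecs <- list()
  for (m in config$methods) {
    for (id in names(profiles)) {
      ev <- tryCatch(
        looEvaluate(profiles[[id]], m, params = config$params[[m]] %||% list(),
                    seed = config$seed),
        error = function(e) e)
      if (inherits(ev, "error")) {
        note("method ", m, " failed on ", id, ": ", conditionMessage(ev))
        next
      }
      evals[[paste(m, id, sep = ".")]] <- ev
      allRecs[[paste(m, id, sep = ".")]] <- records(ev)
    }
    note("evaluated ", m)
  }
  recs <- do.call(rbind, c(allRecs, list(make.row.names = FALSE)))
  writeTable(recs, "records.tsv")
  writeTable(summarizeAccuracy(recs, "method"), "summary_method.tsv")
  writeTable(summarizeAccuracy(recs, c("method", "individual_id")),
             "summary_individual.tsv")

  # ---- stability tables ----
  stabRows <- list()
  for (id in names(profiles)) {
    p <- profiles[[id]]
    idx <- seq(2L, nSamples(p) - 1L)
    st <- vapply(idx, function(i)
      suppressWarnings(as.numeric(timepointStability(p, i))), numeric(1))
    stabRows[[id]] <- data.frame(individual_id = id, target_index = idx,
                                 target_time = sampleTimes(p)[idx],
                                 stability = st)
  }
  writeTable(do.call(rbind, c(stabRows, list(make.row.names = FALSE))),
             "stability.tsv")
  writeTable(taxonBimodalityTable(profiles), "bimodality.tsv")

  # ---- subsampling experiment ----
  if (!is.null(config$subsampleSizes)) {
    sub <- list()
    for (m in config$methods) {
      for (id in names(profiles)) {
        res <- tryCatch(
          suppressWarnings(subsampleExperiment(
            profiles[[id]], m, sizes = config$subsampleSizes,
            replicates = config$subsampleReplicates,
            params = config$params[[m]] %||% list(), seed = config$seed)),
          error = function(e) NULL)
        if (!is.null(res)) sub[[paste(m, id, sep = ".")]] <- res
      }
    }
    writeTable(do.call(rbind, c(sub, list(make.row.names = FALSE))),
               "subsample.tsv")
    note("subsampling experiment done")
  }

  # ---- accuracy model ----
  if (isTRUE(config$accuracyModel)) {
    for (m in config$methods) {
      mrecs <- recs[recs$method == m, , drop = FALSE]
      fitRes <- tryCatch(withCallingHandlers({
        feats <- buildAccuracyFeatures(mrecs)
        fit <- fitAccuracyLMM(feats)
        pred <- predictAccuracy(fit, feats)
        writeTable(fixedEffects(fit), paste0("accuracy_model_", m, ".tsv"))
        writeTable(cbind(feats[c("individual_id", "target_time",
                                 "bc_similarity")],
                         predicted_bc = as.numeric(pred)),
                   paste0("accuracy_predictions_", m, ".tsv"))
        TRUE
      }, warning = function(w) {
        note("accuracy model warning for ", m, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }), error = function(e) {
        note("accuracy model failed for ", m, ": ", conditionMessage(e))
        FALSE
      })
      if (fitRes) note("accuracy model fitted for ", m)
    }
  }

  manifest <- list(
    package = "micropolate",
    version = as.character(utils::packageVersion("micropolate")),
    seed = config$seed,
    methods = config$methods,
    n_profiles = length(profiles),
    synthetic = is.null(config$input),
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(logLines, logPath)
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
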