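#' @rdname LongitudinalProfile-class
#' @param object,x a `LongitudinalProfile` (or other package object).
#' @export
setGeneric("individualId", function(object) standardGeneric("individualId"))

#' @rdname LongitudinalProfile-class
#' @export
setGeneric("datasetLabel", function(object) standardGeneric("datasetLabel"))

#' @rdname LongitudinalProfile-class
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname LongitudinalProfile-class
#' @export
setGeneric("abundanceMatrix", function(object) standardGeneric("abundanceMatrix"))

#' @rdname LongitudinalProfile-class
#' @export
setGeneric("taxa", function(object) standardGeneric("taxa"))

#' @rdname LongitudinalProfile-class
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname LongitudinalProfile-class
#' @export
setGeneric("nTaxa", function(object) standardGeneric("nTaxa"))

#' Extract the tidy per-target record table from an evaluation
#' @param object a [LooEvaluation-class] object.
#' @return a data.frame, one row per leave-one-out target.
#' @export
setGeneric("records", function(object) standardGeneric("records"))

#' Extract the per-taxon relative-error matrix from an evaluation
#' @param object a [LooEvaluation-class] object.
#' @export
setGeneric("relativeErrors", function(object) standardGeneric("relativeErrors"))

#' Fixed-effect coefficient table (with Wald statistics)
#' @param object an [AccuracyModelFit-class] object.
#' @export
setGeneric("fixedEffects", function(object) standardGeneric("fixedEffects"))
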