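#' Accessors for restMVPA objects
#'
#' Small accessor generics used across the package: `tsData` returns the
#' T x V signal matrix of a [RoiTimeSeries-class], `trSec` its repetition
#' time, `nVolumes`/`nVoxels` its dimensions, `sessionId` its session label,
#' `taskFraction` the task-labelled percentage of a [RestLabeling-class],
#' `windowLabels` its per-window labels, and `eventTable` the events
#' data.frame of a [BlockEvents-class].
#'
#' @param x an object of the documented class.
#' @return the slot value described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))

#' @rdname accessors
#' @export
setGeneric("trSec", function(x) standardGeneric("trSec"))

#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))

#' @rdname accessors
#' @export
setGeneric("taskFraction", function(x) standardGeneric("taskFraction"))

#' @rdname accessors
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setMethod("tsData", "RoiTimeSeries", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("trSec", "RoiTimeSeries", function(x) x@trSec)

#' @rdname accessors
#' @export
setMethod("nVolumes", "RoiTimeSeries", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("nVoxels", "RoiTimeSeries", function(x) ncol(x@data))

#' @rdname accessors
#' @export
setMethod("sessionId", "RoiTimeSeries", function(x) x@sessionId)

#' @rdname accessors
#' @export
setMethod("nVoxels", "RoiMask", function(x) nrow(x@voxelIndices))

#' @rdname accessors
#' @export
setMethod("taskFraction", "RestLabeling", function(x) x@taskFraction)

#' @rdname accessors
#' @export
setMethod("windowLabels", "RestLabeling", function(x) x@windowLabels)

#' @rdname accessors
#' @export
setMethod("eventTable", "BlockEvents", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("sessionId", "BlockEvents", function(x) x@sessionId)

#' Number of samples in a SampleSet
#' @param x a [SampleSet-class].
#' @return integer sample count.
#' @export
setMethod("length", "SampleSet", function(x) nrow(x@features))

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf(
    "RoiTimeSeries: %d volumes x %d voxels (TR %.1f s)\n",
    nrow(object@data), ncol(object@data), object@trSec))
  cat(sprintf("  subject %s, session %s\n", object@subjectId, object@sessionId))
  fl <- if (length(object@flags)) paste(object@flags, collapse = ", ") else "none"
  cat(sprintf("  preprocessing: %s\n", fl))
})

setMethod("show", "BlockEvents", function(object) {
  tab <- table(object@events$trial_type)
  cat(sprintf("BlockEvents: session %s, %d blocks (%s)\n",
    object@sessionId, nrow(object@events),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "SampleSet", function(object) {
  tab <- table(object@labels)
  cat(sprintf(
    "SampleSet: %d samples, window %d volumes x %d voxels (%d features)\n",
    nrow(object@features), object@windowLen, object@nVoxels,
    ncol(object@features)))
  cat(sprintf("  labels: %s\n",
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "DecoderModel", function(object) {
  cat(sprintf(
    "DecoderModel: linear SVM (C = %g), %d features (window %d x %d voxels)\n",
    object@C, length(object@weights), object@windowLen, object@nVoxels))
  cat(sprintf("  trained on sessions: %s\n",
    paste(object@trainingSessions, collapse = ", ")))
})

setMethod("show", "TemplatePair", function(object) {
  cat(sprintf(
    "TemplatePair: window %d x %d voxels; source blocks task=%d, nontask=%d\n",
    object@windowLen, object@nVoxels,
    object@nSourceBlocks[["task"]], object@nSourceBlocks[["nontask"]]))
})

setMethod("show", "RestLabeling", function(object) {
  cat(sprintf(
    "RestLabeling (%s): session %s, %d windows, %.1f%% task-labelled\n",
    object@method, object@sessionId, length(object@windowLabels),
    object@taskFraction))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: synthetic block-design BOLD study\n")
  cat(sprintf("  %d voxels, TR %.1f s; %d task sessions (%d+%d blocks of %.0f s)\n",
    object@nVoxels, object@trSec, object@nTaskSessions,
    object@blocksPerCondition, object@blocksPerCondition,
    object@blockDurationSec))
  cat(sprintf("  %d task / %d rest scans, %d discarded\n",
    object@taskScans, object@restScans, object@discardVolumes))
  cat(sprintf("  amplitude %.2f, noise sd %.2f (AR1 %.2f), drift %.1f @ %.0f s\n",
    object@patternAmplitude, object@noiseSd, object@ar1Coef,
    object@driftAmplitude, object@driftPeriodSec))
  cat(sprintf("  rest events: pre %d, post %d (%.0f s each)\n",
    object@nReactEventsPre, object@nReactEventsPost,
    object@reactEventDurationSec))
})

setMethod("show", "SyntheticSubject", function(object) {
  cat(sprintf("SyntheticSubject %s (%s): %d task sessions, pre/post rest\n",
    object@subjectId, object@group, length(object@taskSessions)))
  cat(sprintf("  true task-window fraction: pre %.1f%%, post %.1f%%\n",
    object@trueFraction[["pre"]], object@trueFraction[["post"]]))
})
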