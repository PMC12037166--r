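#' @import methods
NULL

#' Simulation configuration for synthetic block-design BOLD datasets
#'
#' An S4 container for the design constants of the simulated experiment:
#' four task sessions of interleaved 12 s task and replay blocks, two 6 min
#' resting-state runs (one before, one after the first three task sessions),
#' TR 3 s, 174 task-session and 122 rest-session volumes of which the first
#' three are discarded. The noise model is per-voxel AR(1) plus a shared
#' cosine drift and linear trend; reactivation events planted in rest runs
#' are HRF-convolved re-insertions of the task pattern.
#'
#' @slot nVoxels number of ROI voxels (V).
#' @slot trSec repetition time in seconds.
#' @slot nTaskSessions number of task sessions per subject.
#' @slot blocksPerCondition blocks per condition per task session.
#' @slot blockDurationSec block duration in seconds.
#' @slot interBlockGapSec fixation gap between consecutive blocks, seconds.
#' @slot initialFixationSec fixation before the first block, seconds.
#' @slot taskScans volumes acquired per task session (before discarding).
#' @slot restScans volumes acquired per rest session (before discarding).
#' @slot discardVolumes initial volumes discarded for T1 equilibration.
#' @slot patternAmplitude amplitude of the planted condition patterns
#'   (signal units, percent-signal scale).
#' @slot noiseSd innovation standard deviation of the AR(1) voxel noise.
#' @slot ar1Coef AR(1) coefficient in `[0, 1)`.
#' @slot driftAmplitude amplitude of the shared cosine drift.
#' @slot driftPeriodSec period of the cosine drift in seconds.
#' @slot linearTrendAmplitude half-range of the shared centred linear trend.
#' @slot nReactEventsPre planted reactivation events in the pre-task rest run.
#' @slot nReactEventsPost planted reactivation events in the post-task rest
#'   run (the experimental dial).
#' @slot reactEventDurationSec duration of one reactivation event, seconds.
#' @slot patternCorrelation target correlation between the task and replay
#'   patterns (default 0: orthogonal).
#' @slot behaviorCoupling slope of behavioural improvement on the true
#'   reactivation-fraction increase, error units per percentage point.
#' @slot behaviorNoiseSd standard deviation of behavioural noise, error units.
#' @slot baselineError mean tracking error at session 1, error units.
#' @slot learningDecrement within-task learning: error decrease per session.
#'
#' @seealso [simConfig()] for the user-facing constructor.
#' @export
setClass("SimConfig",
  representation(
    nVoxels = "integer",
    trSec = "numeric",
    nTaskSessions = "integer",
    blocksPerCondition = "integer",
    blockDurationSec = "numeric",
    interBlockGapSec = "numeric",
    initialFixationSec = "numeric",
    taskScans = "integer",
    restScans = "integer",
    discardVolumes = "integer",
    patternAmplitude = "numeric",
    noiseSd = "numeric",
    ar1Coef = "numeric",
    driftAmplitude = "numeric",
    driftPeriodSec = "numeric",
    linearTrendAmplitude = "numeric",
    nReactEventsPre = "integer",
    nReactEventsPost = "integer",
    reactEventDurationSec = "numeric",
    patternCorrelation = "numeric",
    behaviorCoupling = "numeric",
    behaviorNoiseSd = "numeric",
    baselineError = "numeric",
    learningDecrement = "numeric"
  ),
  prototype(
    nVoxels = 200L,
    trSec = 3.0,
    nTaskSessions = 4L,
    blocksPerCondition = 10L,
    blockDurationSec = 12,
    interBlockGapSec = 6,
    initialFixationSec = 9,
    taskScans = 174L,
    restScans = 122L,
    discardVolumes = 3L,
    patternAmplitude = 1.0,
    noiseSd = 1.0,
    ar1Coef = 0.3,
    driftAmplitude = 2.0,
    driftPeriodSec = 300,
    linearTrendAmplitude = 1.0,
    nReactEventsPre = 0L,
    nReactEventsPost = 6L,
    reactEventDurationSec = 12,
    patternCorrelation = 0,
    behaviorCoupling = 0.3,
    behaviorNoiseSd = 3,
    baselineError = 40,
    learningDecrement = 5
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nVoxels < 1L) msg <- c(msg, "nVoxels must be >= 1")
  if (object@trSec <= 0) msg <- c(msg, "trSec must be > 0")
  if (object@ar1Coef < 0 || object@ar1Coef >= 1)
    msg <- c(msg, "ar1Coef must lie in [0, 1)")
  if (object@discardVolumes < 0L) msg <- c(msg, "discardVolumes must be >= 0")
  ## the block design (including initial fixation) must fit in the run
  design <- object@initialFixationSec +
    2 * object@blocksPerCondition *
      (object@blockDurationSec + object@interBlockGapSec) -
    object@interBlockGapSec
  if (design > object@taskScans * object@trSec)
    msg <- c(msg, sprintf(
      "block design needs %.0f s but the task run has only %.0f s (taskScans*trSec)",
      design, object@taskScans * object@trSec))
  if (abs(object@patternCorrelation) > 1)
    msg <- c(msg, "patternCorrelation must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Condition and activation patterns planted in a simulated subject
#'
#' @slot patternTask unit-norm length-V task pattern.
#' @slot patternReplay unit-norm length-V replay (control) pattern.
#' @slot patternCorrelation realised correlation between the two patterns.
#' @export
setClass("GroundTruth",
  representation(
    patternTask = "numeric",
    patternReplay = "numeric",
    patternCorrelation = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (length(object@patternTask) != length(object@patternReplay))
    msg <- c(msg, "patternTask and patternReplay must have equal length")
  if (abs(sqrt(sum(object@patternTask^2)) - 1) > 1e-8)
    msg <- c(msg, "patternTask must have unit Euclidean norm")
  if (abs(sqrt(sum(object@patternReplay^2)) - 1) > 1e-8)
    msg <- c(msg, "patternReplay must have unit Euclidean norm")
  if (length(msg)) msg else TRUE
})

#' ROI BOLD time series for one session
#'
#' A T x V matrix of BOLD signal (volumes in rows, ROI voxels in columns)
#' together with its repetition time and provenance. Preprocessing state is
#' tracked through `flags`; the pipeline order discard -> filter -> z-norm
#' is enforced by the preprocessing functions.
#'
#' @slot data numeric T x V matrix, no missing values.
#' @slot trSec repetition time in seconds.
#' @slot sessionId session label.
#' @slot subjectId subject label.
#' @slot flags subset of `c("discarded", "filtered", "znormed")`.
#' @slot nDiscarded number of initial volumes already removed.
#' @slot constantVoxels 0-based indices of voxels that were constant at
#'   z-normalisation time (their columns are all zero).
#' @export
setClass("RoiTimeSeries",
  representation(
    data = "matrix",
    trSec = "numeric",
    sessionId = "character",
    subjectId = "character",
    flags = "character",
    nDiscarded = "integer",
    constantVoxels = "integer"
  ),
  prototype(
    trSec = 3.0, sessionId = "unknown", subjectId = "unknown",
    flags = character(), nDiscarded = 0L, constantVoxels = integer()
  )
)

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  if (nrow(object@data) < 1L || ncol(object@data) < 1L)
    msg <- c(msg, "data must have at least one row and one column")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite with no missing values")
  if (object@trSec <= 0) msg <- c(msg, "trSec must be > 0")
  bad <- setdiff(object@flags, c("discarded", "filtered", "znormed"))
  if (length(bad)) msg <- c(msg, paste("unknown flags:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Binary region-of-interest mask over a 3D voxel grid
#'
#' @slot gridShape integer length-3 grid dimensions.
#' @slot voxelIndices integer V x 3 matrix of 0-based voxel coordinates; the
#'   row order is the canonical voxel ordering used by every downstream
#'   feature vector.
#' @export
setClass("RoiMask",
  representation(gridShape = "integer", voxelIndices = "matrix")
)

setValidity("RoiMask", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L)
    msg <- c(msg, "gridShape must have length 3")
  vi <- object@voxelIndices
  if (ncol(vi) != 3L) msg <- c(msg, "voxelIndices must have 3 columns")
  if (nrow(vi) < 1L) msg <- c(msg, "mask must contain at least one voxel")
  else {
    if (any(vi < 0) || any(t(vi) >= object@gridShape))
      msg <- c(msg, "voxelIndices out of grid bounds")
    if (anyDuplicated(vi)) msg <- c(msg, "voxelIndices must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Ordered condition blocks for one task session
#'
#' Onsets are in seconds from the start of the acquired run (before volume
#' discarding), following the BIDS events convention.
#'
#' @slot events data.frame with columns `onset`, `duration` (seconds) and
#'   `trial_type` (one of "task", "replay").
#' @slot sessionId session label.
#' @export
setClass("BlockEvents",
  representation(events = "data.frame", sessionId = "character"),
  prototype(sessionId = "unknown")
)

setValidity("BlockEvents", function(object) {
  ev <- object@events
  msg <- character()
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    msg <- c(msg, "events must have columns onset, duration, trial_type")
  else {
    if (!is.numeric(ev$onset) || !is.numeric(ev$duration))
      msg <- c(msg, "onset and duration must be numeric")
    else if (any(ev$duration <= 0)) msg <- c(msg, "durations must be positive")
    if (!all(ev$trial_type %in% c("task", "replay")))
      msg <- c(msg, "trial_type must be 'task' or 'replay'")
    if (is.unsorted(ev$onset)) msg <- c(msg, "events must be ordered by onset")
  }
  if (length(msg)) msg else TRUE
})

#' A set of spatiotemporal samples sharing one feature contract
#'
#' Each row of `features` is one sample: `windowLen` consecutive volumes of a
#' session, flattened with volume order preserved so that feature index
#' `l * V + v` (0-based) is voxel `v` at window volume `l`.
#'
#' @slot features numeric n x (windowLen * nVoxels) matrix.
#' @slot labels character vector in `c("task", "replay", "unknown")`.
#' @slot sessionId per-sample session label.
#' @slot startVolume 0-based retained-volume index of each window start.
#' @slot windowLen window length L in volumes.
#' @slot nVoxels number of voxels V.
#' @export
setClass("SampleSet",
  representation(
    features = "matrix",
    labels = "character",
    sessionId = "character",
    startVolume = "integer",
    windowLen = "integer",
    nVoxels = "integer"
  )
)

setValidity("SampleSet", function(object) {
  msg <- character()
  n <- nrow(object@features)
  if (ncol(object@features) != object@windowLen * object@nVoxels)
    msg <- c(msg, "feature width must equal windowLen * nVoxels")
  if (length(object@labels) != n || length(object@sessionId) != n ||
      length(object@startVolume) != n)
    msg <- c(msg, "labels, sessionId and startVolume must match sample count")
  if (!all(object@labels %in% c("task", "replay", "unknown")))
    msg <- c(msg, "labels must be 'task', 'replay' or 'unknown'")
  if (any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite")
  if (length(msg)) msg else TRUE
})

#' Linear decoder separating task from replay spatiotemporal patterns
#'
#' Stores the primal weights and bias of a linear soft-margin SVM so that a
#' window `x` is labelled task iff `sum(w * x) + b > 0`; a decision value of
#' exactly zero is labelled non-task.
#'
#' @slot weights length `windowLen * nVoxels` weight vector, oriented so
#'   positive decision values mean "task".
#' @slot bias scalar intercept.
#' @slot C soft-margin penalty used in training.
#' @slot trainingSessions labels of the sessions the model was trained on.
#' @slot windowLen,nVoxels the feature contract the model expects.
#' @export
setClass("DecoderModel",
  representation(
    weights = "numeric",
    bias = "numeric",
    C = "numeric",
    trainingSessions = "character",
    windowLen = "integer",
    nVoxels = "integer"
  )
)

setValidity("DecoderModel", function(object) {
  msg <- character()
  if (length(object@weights) != object@windowLen * object@nVoxels)
    msg <- c(msg, "weights length must equal windowLen * nVoxels")
  if (any(!is.finite(object@weights)) || !is.finite(object@bias))
    msg <- c(msg, "weights and bias must be finite")
  if (length(msg)) msg else TRUE
})

#' Class-mean spatiotemporal templates for nearest-template classification
#'
#' @slot taskTemplate,nontaskTemplate arithmetic means of the training task
#'   and replay (non-task) sample vectors.
#' @slot nSourceBlocks named integer vector: samples per class.
#' @slot windowLen,nVoxels the feature contract.
#' @export
setClass("TemplatePair",
  representation(
    taskTemplate = "numeric",
    nontaskTemplate = "numeric",
    nSourceBlocks = "integer",
    windowLen = "integer",
    nVoxels = "integer"
  )
)

setValidity("TemplatePair", function(object) {
  msg <- character()
  d <- object@windowLen * object@nVoxels
  if (length(object@taskTemplate) != d || length(object@nontaskTemplate) != d)
    msg <- c(msg, "template length must equal windowLen * nVoxels")
  if (any(!is.finite(object@taskTemplate)) ||
      any(!is.finite(object@nontaskTemplate)))
    msg <- c(msg, "templates must be finite")
  if (length(msg)) msg else TRUE
})

#' Window-level labelling of one resting-state run
#'
#' @slot windowLabels ordered per-window labels, "task" or "nontask".
#' @slot taskFraction percentage of windows labelled task.
#' @slot sessionId rest-session label.
#' @slot method "svm" or "rsa".
#' @export
setClass("RestLabeling",
  representation(
    windowLabels = "character",
    taskFraction = "numeric",
    sessionId = "character",
    method = "character"
  )
)

setValidity("RestLabeling", function(object) {
  msg <- character()
  if (!all(object@windowLabels %in% c("task", "nontask")))
    msg <- c(msg, "window labels must be 'task' or 'nontask'")
  expect <- 100 * mean(object@windowLabels == "task")
  if (length(object@windowLabels) &&
      abs(object@taskFraction - expect) > 1e-8)
    msg <- c(msg, "taskFraction must equal 100 * (#task windows)/(#windows)")
  if (!object@method %in% c("svm", "rsa"))
    msg <- c(msg, "method must be 'svm' or 'rsa'")
  if (length(msg)) msg else TRUE
})

#' One simulated subject: task sessions, rest runs, behaviour, ground truth
#'
#' @slot subjectId subject label.
#' @slot group hand-use group, "right-hand" or "left-hand".
#' @slot taskSessions list of `list(ts = RoiTimeSeries, events = BlockEvents)`.
#' @slot restPre,restPost raw (undiscarded) rest-run RoiTimeSeries.
#' @slot restEventOnsets list with elements `pre` and `post`: 0-based
#'   retained-volume onset indices of planted reactivation events.
#' @slot trueFraction named numeric (`pre`, `post`): percentage of rest
#'   windows overlapping a planted event.
#' @slot behavior tracking error per task session (positive, error units).
#' @slot truth the GroundTruth patterns used to build the subject.
#' @export
setClass("SyntheticSubject",
  representation(
    subjectId = "character",
    group = "character",
    taskSessions = "list",
    restPre = "RoiTimeSeries",
    restPost = "RoiTimeSeries",
    restEventOnsets = "list",
    trueFraction = "numeric",
    behavior = "numeric",
    truth = "GroundTruth"
  )
)

setValidity("SyntheticSubject", function(object) {
  msg <- character()
  if (!object@group %in% c("right-hand", "left-hand"))
    msg <- c(msg, "group must be 'right-hand' or 'left-hand'")
  if (any(object@behavior <= 0))
    msg <- c(msg, "behaviour (tracking error) must be positive")
  if (length(msg)) msg else TRUE
})
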