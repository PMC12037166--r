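#' Train the linear SVM task-vs-replay decoder
#'
#' Fits a soft-margin linear support vector machine (libsvm via
#' \pkg{e1071}, fixed penalty `C = 1` by default, convergence tolerance
#' 1e-6, no internal rescaling — features are already z-normalised) on
#' labelled spatiotemporal samples, and extracts the primal weight vector and
#' bias oriented so that positive decision values mean "task".
#'
#' @param samples a [SampleSet-class] containing both classes
#'   (`"task"` and `"replay"`).
#' @param C soft-margin penalty (default 1).
#' @return a [DecoderModel-class].
#' @export
trainDecoder <- function(samples, C = 1) {
  labs <- samples@labels
  if (!all(c("task", "replay") %in% labs))
    stop("training data must contain both 'task' and 'replay' samples")
  y <- factor(labs, levels = c("task", "replay"))
  fit <- e1071::svm(samples@features, y, kernel = "linear", cost = C,
                    scale = FALSE, tolerance = 1e-6)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  ## libsvm orients the decision function by the first training label it
  ## sees; pin the orientation to "positive = task" explicitly.
  dv <- attr(stats::predict(fit, samples@features, decision.values = TRUE),
             "decision.values")
  positiveClass <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (positiveClass != "task") {
    w <- -w
    b <- -b
  }
  ## Class= must be named: a `C =` argument would partially match it otherwise
  new(Class = "DecoderModel", weights = as.numeric(w), bias = b, C = C,
      trainingSessions = unique(samples@sessionId),
      windowLen = samples@windowLen, nVoxels = samples@nVoxels)
}

#' Decision values of a decoder on a sample set
#'
#' @param model a [DecoderModel-class].
#' @param samples a [SampleSet-class] with a matching feature contract.
#' @return numeric vector `w'x + b` per sample (positive = task side).
#' @export
decisionValues <- function(model, samples) {
  if (samples@windowLen != model@windowLen ||
      samples@nVoxels != model@nVoxels)
    stop(sprintf(
      "feature contract mismatch: model expects %d x %d (window x voxels), samples are %d x %d",
      model@windowLen, model@nVoxels, samples@windowLen, samples@nVoxels))
  drop(samples@features %*% model@weights) + model@bias
}

#' Leave-one-session-out cross-validated accuracy
#'
#' For each session, trains the decoder on all other sessions and scores the
#' held-out session's labelled blocks.
#'
#' @param samples a labelled [SampleSet-class] spanning >= 2 sessions.
#' @param C soft-margin penalty (default 1).
#' @return list with `meanAccuracy` (percent), `perFold` (named percent per
#'   held-out session) and `folds`.
#' @export
losoAccuracy <- function(samples, C = 1) {
  folds <- losoSplits(samples)
  acc <- vapply(folds, function(f) {
    train <- samples[samples@sessionId %in% f$train]
    test <- samples[samples@sessionId == f$test]
    model <- trainDecoder(train, C = C)
    pred <- ifelse(decisionValues(model, test) > 0, "task", "replay")
    100 * mean(pred == test@labels)
  }, numeric(1))
  names(acc) <- vapply(folds, `[[`, character(1), "test")
  list(meanAccuracy = mean(acc), perFold = acc, folds = folds)
}

#' Score a resting-state run with a trained decoder
#'
#' Labels every sliding window "task" iff its decision value `w'x + b` is
#' strictly positive; a value of exactly zero is labelled non-task
#' (conservative tie rule). The task fraction is the percentage of windows
#' labelled task.
#'
#' @param model a [DecoderModel-class].
#' @param restWindows a [SampleSet-class] of sliding windows (see
#'   [slidingWindows()]).
#' @return a [RestLabeling-class] with `method = "svm"`.
#' @export
scoreRest <- function(model, restWindows) {
  d <- decisionValues(model, restWindows)
  labels <- ifelse(d > 0, "task", "nontask")
  new("RestLabeling",
      windowLabels = labels,
      taskFraction = 100 * mean(labels == "task"),
      sessionId = unique(restWindows@sessionId)[1],
      method = "svm")
}

#' Window-count-weighted combination of rest labellings
#'
#' The task fraction of a concatenation of runs is the window-count-weighted
#' mean of the per-run fractions; this helper makes that explicit.
#'
#' @param ... [RestLabeling-class] objects with the same method.
#' @return a combined [RestLabeling-class].
#' @export
combineLabelings <- function(...) {
  labs <- list(...)
  method <- unique(vapply(labs, function(l) l@method, character(1)))
  if (length(method) != 1L) stop("labelings mix methods")
  all <- unlist(lapply(labs, function(l) l@windowLabels))
  new("RestLabeling", windowLabels = all,
      taskFraction = 100 * mean(all == "task"),
      sessionId = paste(vapply(labs, function(l) l@sessionId, character(1)),
                        collapse = "+"),
      method = method)
}
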