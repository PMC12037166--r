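#' Build class-mean spatiotemporal templates
#'
#' The task template is the arithmetic mean of all training task-block
#' sample vectors; the non-task template the mean of the replay-block
#' vectors.
#'
#' @param samples a labelled [SampleSet-class] containing both classes.
#' @return a [TemplatePair-class].
#' @export
buildTemplates <- function(samples) {
  labs <- samples@labels
  if (!all(c("task", "replay") %in% labs))
    stop("template construction needs both 'task' and 'replay' samples")
  taskRows <- samples@features[labs == "task", , drop = FALSE]
  repRows <- samples@features[labs == "replay", , drop = FALSE]
  new("TemplatePair",
      taskTemplate = colMeans(taskRows),
      nontaskTemplate = colMeans(repRows),
      nSourceBlocks = c(task = nrow(taskRows), nontask = nrow(repRows)),
      windowLen = samples@windowLen, nVoxels = samples@nVoxels)
}

#' Nearest-template classification by Euclidean distance
#'
#' Each window is labelled "task" iff its Euclidean distance to the task
#' template is strictly smaller than its distance to the non-task template;
#' equidistant windows are labelled non-task (same conservative tie rule as
#' the decoder).
#'
#' @param windows a [SampleSet-class] with a matching feature contract.
#' @param templates a [TemplatePair-class].
#' @return character vector of labels, "task" or "nontask".
#' @export
classifyByDistance <- function(windows, templates) {
  if (windows@windowLen != templates@windowLen ||
      windows@nVoxels != templates@nVoxels)
    stop(sprintf(
      "feature contract mismatch: templates are %d x %d (window x voxels), windows are %d x %d",
      templates@windowLen, templates@nVoxels,
      windows@windowLen, windows@nVoxels))
  x <- windows@features
  dTask <- rowSums(sweep(x, 2, templates@taskTemplate, "-")^2)
  dNon <- rowSums(sweep(x, 2, templates@nontaskTemplate, "-")^2)
  ifelse(dTask < dNon, "task", "nontask")
}

#' Score a resting-state run by nearest template
#'
#' Sliding-window analogue of [scoreRest()] using the template distances
#' instead of the decoder.
#'
#' @param templates a [TemplatePair-class].
#' @param restWindows a [SampleSet-class] of sliding windows.
#' @return a [RestLabeling-class] with `method = "rsa"`.
#' @export
scoreRestRsa <- function(templates, restWindows) {
  labels <- classifyByDistance(restWindows, templates)
  new("RestLabeling",
      windowLabels = labels,
      taskFraction = 100 * mean(labels == "task"),
      sessionId = unique(restWindows@sessionId)[1],
      method = "rsa")
}
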