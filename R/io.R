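#' Build a compact ROI mask for embedding V voxels in a 3D grid
#'
#' Used when writing simulated ROI-space data as 4D NIfTI: voxels are laid
#' out in the canonical (x-fastest) order inside the smallest near-cubic
#' grid that holds them.
#'
#' @param nVoxels number of ROI voxels.
#' @return a [RoiMask-class].
#' @export
makeRoiMask <- function(nVoxels) {
  nx <- ceiling(nVoxels^(1 / 3))
  ny <- ceiling(sqrt(nVoxels / nx))
  nz <- ceiling(nVoxels / (nx * ny))
  lin <- 0:(nVoxels - 1)
  new("RoiMask",
      gridShape = as.integer(c(nx, ny, nz)),
      voxelIndices = cbind(lin %% nx,
                           (lin %/% nx) %% ny,
                           lin %/% (nx * ny)))
}

## Embed a T x V series into a 4D array on the mask grid.
embedSeries <- function(ts, mask) {
  dims <- c(mask@gridShape, nrow(ts@data))
  arr <- array(0, dims)
  nSpace <- prod(mask@gridShape)
  lin <- 1L + mask@voxelIndices[, 1] +
    dims[1] * (mask@voxelIndices[, 2] + dims[2] * mask@voxelIndices[, 3])
  flat <- matrix(arr, nSpace, dims[4])
  flat[lin, ] <- t(ts@data)
  array(flat, dims)
}

#' Write / read NIfTI volumes and masks
#'
#' Thin wrappers around \pkg{RNifti}: 4D BOLD images are stored as float32,
#' masks as binary volumes whose nonzero voxels (in canonical x-fastest
#' order) define the ROI.
#'
#' @param ts a [RoiTimeSeries-class]; `mask` a [RoiMask-class]; `file` a
#'   path ending in `.nii` or `.nii.gz`.
#' @return `writeBold`/`writeMask` return the file path invisibly;
#'   `readBold` returns a 4D array; `readMask` a [RoiMask-class].
#' @name niftiIO
NULL

#' @rdname niftiIO
#' @export
writeBold <- function(ts, mask, file) {
  img <- RNifti::asNifti(embedSeries(ts, mask),
                         pixdim = c(3, 3, 3, ts@trSec))
  RNifti::writeNifti(img, file, datatype = "float")
  invisible(file)
}

#' @rdname niftiIO
#' @export
readBold <- function(file) {
  arr <- RNifti::readNifti(file)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI image: ", file)
  unclass(arr)[, , , , drop = FALSE]
}

#' @rdname niftiIO
#' @export
writeMask <- function(mask, file) {
  arr <- array(0L, mask@gridShape)
  arr[1L + mask@voxelIndices[, 1] +
        mask@gridShape[1] * (mask@voxelIndices[, 2] +
                             mask@gridShape[2] * mask@voxelIndices[, 3])] <- 1L
  RNifti::writeNifti(RNifti::asNifti(arr), file, datatype = "uint8")
  invisible(file)
}

#' @rdname niftiIO
#' @export
readMask <- function(file) {
  arr <- RNifti::readNifti(file)
  dims <- dim(arr)
  if (length(dims) != 3L) stop("expected a 3D NIfTI mask: ", file)
  lin <- which(arr != 0) - 1L
  if (!length(lin)) stop("mask is empty: ", file)
  new("RoiMask",
      gridShape = as.integer(dims),
      voxelIndices = cbind(lin %% dims[1],
                           (lin %/% dims[1]) %% dims[2],
                           lin %/% (dims[1] * dims[2])))
}

#' Write / read BIDS-style events tables
#'
#' Tab-separated tables with columns `onset`, `duration` (seconds from run
#' start, before volume discarding) and `trial_type` (task/replay). Reading
#' validates every row and reports the offending line on failure.
#'
#' @param events a [BlockEvents-class]; `file` a `.tsv` path; `sessionId`
#'   the session label to attach on read.
#' @return `writeEventsTsv` returns the path invisibly; `readEventsTsv` a
#'   [BlockEvents-class].
#' @name eventsIO
NULL

#' @rdname eventsIO
#' @export
writeEventsTsv <- function(events, file) {
  utils::write.table(events@events, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname eventsIO
#' @export
readEventsTsv <- function(file, sessionId = "unknown") {
  ev <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(ev)))
    stop("events TSV must have columns onset, duration, trial_type: ", file)
  for (i in seq_len(nrow(ev))) {
    if (!is.finite(ev$onset[i]) || ev$onset[i] < 0)
      stop(sprintf("%s line %d: onset must be a non-negative number", file, i + 1L))
    if (!is.finite(ev$duration[i]) || ev$duration[i] <= 0)
      stop(sprintf("%s line %d: duration must be a positive number", file, i + 1L))
    if (!ev$trial_type[i] %in% c("task", "replay"))
      stop(sprintf("%s line %d: trial_type must be 'task' or 'replay'", file, i + 1L))
  }
  new("BlockEvents", events = ev, sessionId = sessionId)
}

#' Save / load a decoder model as JSON
#'
#' The weight vector, bias, penalty, training sessions and feature contract
#' are stored in one JSON file at full double precision.
#'
#' @param model a [DecoderModel-class]; `file` a `.json` path.
#' @return `writeDecoderModel` returns the path invisibly;
#'   `readDecoderModel` the restored [DecoderModel-class].
#' @name modelIO
NULL

#' @rdname modelIO
#' @export
writeDecoderModel <- function(model, file) {
  jsonlite::write_json(list(
    weights = model@weights, bias = model@bias, C = model@C,
    trainingSessions = model@trainingSessions,
    windowLen = model@windowLen, nVoxels = model@nVoxels
  ), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname modelIO
#' @export
readDecoderModel <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  new(Class = "DecoderModel", weights = as.numeric(j$weights), bias = j$bias,
      C = j$C, trainingSessions = as.character(j$trainingSessions),
      windowLen = as.integer(j$windowLen), nVoxels = as.integer(j$nVoxels))
}

#' Write a simulated cohort to disk in standard formats
#'
#' Per subject: one 4D float32 NIfTI per session (task sessions and pre/post
#' rest), a BIDS-style events TSV per task session, and a JSON ground-truth
#' sidecar (patterns, planted onsets, true fractions, behaviour). Shared
#' across subjects: the ROI mask and a behaviour CSV
#' (`subject, session, tracking_error`). The tree round-trips through
#' [readDataset()] at float32 precision.
#'
#' @param subjects list of [SyntheticSubject-class] (see [simulateCohort()]).
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeDataset <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  V <- nVoxels(subjects[[1]]@restPre)
  mask <- makeRoiMask(V)
  writeMask(mask, file.path(dir, "roi_mask.nii.gz"))
  behav <- list()
  for (sub in subjects) {
    sd <- file.path(dir, sub@subjectId)
    dir.create(sd, showWarnings = FALSE)
    for (k in seq_along(sub@taskSessions)) {
      tsk <- sub@taskSessions[[k]]
      writeBold(tsk$ts, mask,
                file.path(sd, sprintf("task%02d_bold.nii.gz", k)))
      writeEventsTsv(tsk$events,
                     file.path(sd, sprintf("task%02d_events.tsv", k)))
    }
    writeBold(sub@restPre, mask, file.path(sd, "rest-pre_bold.nii.gz"))
    writeBold(sub@restPost, mask, file.path(sd, "rest-post_bold.nii.gz"))
    jsonlite::write_json(list(
      subject = sub@subjectId, group = sub@group,
      pattern_task = sub@truth@patternTask,
      pattern_replay = sub@truth@patternReplay,
      pattern_correlation = sub@truth@patternCorrelation,
      rest_event_onsets = sub@restEventOnsets,
      true_fraction = as.list(sub@trueFraction),
      behavior = sub@behavior
    ), file.path(sd, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    behav[[sub@subjectId]] <- data.frame(
      subject = sub@subjectId, session = seq_along(sub@behavior),
      tracking_error = sub@behavior, stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, behav), file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @param trSec repetition time to attach to the series (default 3 s).
#' @return list of [SyntheticSubject-class] (patterns and truth restored
#'   from the JSON sidecars; signal at float32 precision).
#' @export
readDataset <- function(dir, trSec = 3.0) {
  maskFile <- file.path(dir, "roi_mask.nii.gz")
  if (!file.exists(maskFile)) stop("missing ROI mask: ", maskFile)
  mask <- readMask(maskFile)
  behav <- utils::read.csv(file.path(dir, "behavior.csv"),
                           stringsAsFactors = FALSE)
  subDirs <- sort(list.dirs(dir, recursive = FALSE))
  lapply(subDirs, function(sd) {
    sid <- basename(sd)
    j <- jsonlite::read_json(file.path(sd, "ground_truth.json"),
                             simplifyVector = TRUE)
    truth <- new("GroundTruth",
                 patternTask = as.numeric(j$pattern_task),
                 patternReplay = as.numeric(j$pattern_replay),
                 patternCorrelation = j$pattern_correlation)
    taskFiles <- sort(list.files(sd, "^task[0-9]+_bold", full.names = TRUE))
    taskSessions <- lapply(seq_along(taskFiles), function(k) {
      ts <- extractRoi(readBold(taskFiles[k]), mask, trSec,
                       sessionId = sprintf("task%02d", k), subjectId = sid)
      ev <- readEventsTsv(file.path(sd, sprintf("task%02d_events.tsv", k)),
                          sessionId = sprintf("task%02d", k))
      list(ts = ts, events = ev)
    })
    onsets <- lapply(j$rest_event_onsets, as.integer)
    new("SyntheticSubject",
        subjectId = sid, group = j$group,
        taskSessions = taskSessions,
        restPre = extractRoi(readBold(file.path(sd, "rest-pre_bold.nii.gz")),
                             mask, trSec, "rest-pre", sid),
        restPost = extractRoi(readBold(file.path(sd, "rest-post_bold.nii.gz")),
                              mask, trSec, "rest-post", sid),
        restEventOnsets = onsets,
        trueFraction = c(pre = j$true_fraction$pre,
                         post = j$true_fraction$post),
        behavior = behav$tracking_error[behav$subject == sid],
        truth = truth)
  })
}

#' Write a per-voxel statistic map as NIfTI on the mask grid
#'
#' @param values per-voxel statistic (e.g. t-values from [fitContrast()]),
#'   in the mask's canonical voxel order.
#' @param mask the [RoiMask-class] defining the grid.
#' @param file output `.nii`/`.nii.gz` path.
#' @return the path, invisibly.
#' @export
writeStatMap <- function(values, mask, file) {
  if (length(values) != nrow(mask@voxelIndices))
    stop("values length must equal the mask voxel count")
  arr <- array(0, mask@gridShape)
  arr[1L + mask@voxelIndices[, 1] +
        mask@gridShape[1] * (mask@voxelIndices[, 2] +
                             mask@gridShape[2] * mask@voxelIndices[, 3])] <- values
  RNifti::writeNifti(RNifti::asNifti(arr), file, datatype = "float")
  invisible(file)
}
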