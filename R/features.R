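## Flatten a window of volumes into one feature vector: volumes concatenated
## in temporal order, so feature index l*V + v (0-based) is voxel v at window
## volume l.
flattenWindow <- function(data, start0, windowLen) {
  as.vector(t(data[(start0 + 1):(start0 + windowLen), , drop = FALSE]))
}

#' Extract one labelled spatiotemporal sample per block
#'
#' For each block, takes the `windowLen` consecutive retained volumes
#' starting `shiftVolumes` volumes after the block onset (the hemodynamic
#' label shift: 2 TRs = 6 s by default) and flattens them into a feature
#' vector. Blocks whose shifted window runs past the end of the session are
#' dropped with a message.
#'
#' @param ts a fully preprocessed [RoiTimeSeries-class] (all of
#'   `discarded`, `filtered`, `znormed` flags set).
#' @param events a [BlockEvents-class]; onsets must be multiples of the TR
#'   and every duration must equal `windowLen * trSec`.
#' @param shiftVolumes hemodynamic shift in volumes (default 2).
#' @param windowLen window length in volumes (default 4).
#' @return a [SampleSet-class] with one labelled sample per surviving block.
#' @export
epochBlocks <- function(ts, events, shiftVolumes = 2L, windowLen = 4L) {
  if (!all(c("discarded", "filtered", "znormed") %in% ts@flags))
    stop("ts must be fully preprocessed (discard -> filter -> z-norm) before epoching")
  ev <- events@events
  tr <- ts@trSec
  if (any(ev$onset %% tr != 0))
    stop("block onsets must be integer multiples of the TR")
  if (any(ev$duration != windowLen * tr))
    stop(sprintf("block durations must equal windowLen * trSec = %g s",
                 windowLen * tr))
  T <- nrow(ts@data)
  start0 <- as.integer(ev$onset / tr) - ts@nDiscarded + as.integer(shiftVolumes)
  keep <- start0 >= 0L & start0 + windowLen <= T
  if (any(!keep))
    message(sum(!keep), " block(s) dropped: shifted window outside the session")
  starts <- start0[keep]
  feats <- t(vapply(starts, function(s) flattenWindow(ts@data, s, windowLen),
                    numeric(windowLen * ncol(ts@data))))
  new("SampleSet",
      features = feats,
      labels = ev$trial_type[keep],
      sessionId = rep(ts@sessionId, sum(keep)),
      startVolume = starts,
      windowLen = as.integer(windowLen),
      nVoxels = ncol(ts@data))
}

#' Slide a fixed-length window across a session
#'
#' Windows start at retained volumes `0, step, 2*step, ...`; the count is
#' `floor((T - windowLen) / step) + 1`. All labels are `"unknown"`.
#'
#' @param ts a [RoiTimeSeries-class] with at least `windowLen` volumes.
#' @param windowLen window length in volumes (default 4, the block length).
#' @param step advance in volumes per window (default 1).
#' @return a [SampleSet-class] of unlabelled windows.
#' @export
slidingWindows <- function(ts, windowLen = 4L, step = 1L) {
  T <- nrow(ts@data)
  windowLen <- as.integer(windowLen)
  step <- as.integer(step)
  if (T < windowLen)
    stop(sprintf("run of %d volumes is shorter than the %d-volume window",
                 T, windowLen))
  starts <- seq.int(0L, T - windowLen, by = step)
  feats <- t(vapply(starts, function(s) flattenWindow(ts@data, s, windowLen),
                    numeric(windowLen * ncol(ts@data))))
  new("SampleSet",
      features = feats,
      labels = rep("unknown", length(starts)),
      sessionId = rep(ts@sessionId, length(starts)),
      startVolume = as.integer(starts),
      windowLen = windowLen,
      nVoxels = ncol(ts@data))
}

#' Combine sample sets sharing one feature contract
#'
#' @param ... [SampleSet-class] objects with identical `windowLen` and
#'   `nVoxels`.
#' @return the row-bound [SampleSet-class].
#' @export
combineSamples <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "SampleSet"))
    sets <- sets[[1]]
  L <- unique(vapply(sets, function(s) s@windowLen, integer(1)))
  V <- unique(vapply(sets, function(s) s@nVoxels, integer(1)))
  if (length(L) != 1L || length(V) != 1L)
    stop("sample sets have incompatible feature contracts")
  new("SampleSet",
      features = do.call(rbind, lapply(sets, function(s) s@features)),
      labels = unlist(lapply(sets, function(s) s@labels)),
      sessionId = unlist(lapply(sets, function(s) s@sessionId)),
      startVolume = unlist(lapply(sets, function(s) s@startVolume)),
      windowLen = L, nVoxels = V)
}

#' Subset a SampleSet by row index
#' @param x a [SampleSet-class].
#' @param i integer or logical row index.
#' @param j,...,drop ignored.
#' @return the subset [SampleSet-class].
#' @export
setMethod("[", "SampleSet", function(x, i, j, ..., drop = FALSE) {
  new("SampleSet",
      features = x@features[i, , drop = FALSE],
      labels = x@labels[i],
      sessionId = x@sessionId[i],
      startVolume = x@startVolume[i],
      windowLen = x@windowLen, nVoxels = x@nVoxels)
})

#' Leave-one-session-out split plan
#'
#' One fold per distinct session; fold k tests on session k and trains on
#' all others.
#'
#' @param samples a labelled [SampleSet-class] spanning >= 2 sessions.
#' @return list of folds, each `list(train = <session ids>, test = <id>)`.
#' @export
losoSplits <- function(samples) {
  sessions <- unique(samples@sessionId)
  if (length(sessions) < 2L)
    stop("leave-one-session-out needs at least 2 sessions")
  lapply(sessions, function(s)
    list(train = setdiff(sessions, s), test = s))
}
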