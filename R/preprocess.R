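#' Discard initial volumes of a session
#'
#' Removes the first `n` volumes (T1-equilibration scans; 3 by default) and
#' marks the series as discarded. This is the first, mandatory step of the
#' temporal preprocessing pipeline (discard -> high-pass filter -> z-norm).
#'
#' @param ts a [RoiTimeSeries-class].
#' @param n number of initial volumes to remove (default 3); must be < T.
#' @return the trimmed [RoiTimeSeries-class] with the `"discarded"` flag set
#'   and `nDiscarded` recorded.
#' @export
discardInitial <- function(ts, n = 3L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  if (n >= nrow(ts@data))
    stop(sprintf("cannot discard %d volumes from a %d-volume run", n,
                 nrow(ts@data)))
  ts@data <- ts@data[(n + 1L):nrow(ts@data), , drop = FALSE]
  ts@nDiscarded <- ts@nDiscarded + n
  ts@flags <- union(ts@flags, "discarded")
  ts
}

#' High-pass filter voxel time series with a DCT drift basis
#'
#' Removes low-frequency drift by regressing each voxel series on a constant
#' plus the `K = floor(2 * T * trSec / cutoffSec)` leading DCT-II basis
#' vectors `cos(pi * k * (2t + 1) / (2T))`, `k = 1..K` — the discrete-cosine
#' set whose periods exceed the cutoff — and keeping the residuals. The mean
#' is removed with the drift.
#'
#' @param ts a [RoiTimeSeries-class]; the `"discarded"` flag must be set.
#' @param cutoffSec cutoff period in seconds (default 128); must exceed
#'   `2 * trSec`.
#' @return the filtered, mean-centred [RoiTimeSeries-class] with the
#'   `"filtered"` flag set.
#' @export
dctHighpass <- function(ts, cutoffSec = 128) {
  if (!"discarded" %in% ts@flags)
    stop("pipeline order violated: discardInitial() must run before dctHighpass()")
  if (cutoffSec <= 2 * ts@trSec)
    stop("cutoffSec must exceed 2 * trSec")
  T <- nrow(ts@data)
  K <- dctK(T, ts@trSec, cutoffSec)
  X <- cbind(1, dctBasis(T, K))
  ts@data <- qr.resid(qr(X), ts@data)
  ts@flags <- union(ts@flags, "filtered")
  ts
}

#' z-normalise each voxel time series
#'
#' Standardises every voxel column by its own within-session mean and sample
#' standard deviation (denominator T - 1). Constant columns cannot be
#' standardised; they are set to all zeros and their indices recorded in
#' `constantVoxels` so decoder input stays finite.
#'
#' @param ts a [RoiTimeSeries-class]; the `"filtered"` flag must be set.
#' @return the z-normalised [RoiTimeSeries-class] with the `"znormed"` flag.
#' @export
zscoreVoxels <- function(ts) {
  if (!"filtered" %in% ts@flags)
    stop("pipeline order violated: dctHighpass() must run before zscoreVoxels()")
  x <- ts@data
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  const <- which(sdv == 0 | !is.finite(sdv))
  sdv[const] <- 1
  x <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  if (length(const)) x[, const] <- 0
  ts@data <- x
  ts@constantVoxels <- as.integer(const - 1L)
  ts@flags <- union(ts@flags, "znormed")
  ts
}

#' Run the full temporal preprocessing pipeline
#'
#' Convenience wrapper applying [discardInitial()], [dctHighpass()] and
#' [zscoreVoxels()] in the enforced order.
#'
#' @param ts a raw [RoiTimeSeries-class].
#' @param nDiscard initial volumes to drop (default 3).
#' @param cutoffSec high-pass cutoff period in seconds (default 128).
#' @return the fully preprocessed [RoiTimeSeries-class].
#' @export
preprocessSession <- function(ts, nDiscard = 3L, cutoffSec = 128) {
  zscoreVoxels(dctHighpass(discardInitial(ts, nDiscard), cutoffSec))
}

#' Extract ROI voxel time series from a 4D image
#'
#' @param volumes 4D numeric array (x, y, z, t).
#' @param mask a [RoiMask-class] whose grid matches the image grid; the
#'   mask's voxel ordering defines the column order of the result.
#' @param trSec repetition time of the acquisition.
#' @param sessionId,subjectId labels stored in the result.
#' @return a raw [RoiTimeSeries-class] (T x V).
#' @export
extractRoi <- function(volumes, mask, trSec = 3.0,
                       sessionId = "unknown", subjectId = "unknown") {
  dims <- dim(volumes)
  if (length(dims) != 4L)
    stop("volumes must be a 4D array (x, y, z, t); got dimensions ",
         paste(dims, collapse = " x "))
  if (!all(dims[1:3] == mask@gridShape))
    stop(sprintf("grid mismatch: image %s vs mask %s",
                 paste(dims[1:3], collapse = "x"),
                 paste(mask@gridShape, collapse = "x")))
  T <- dims[4]
  V <- nrow(mask@voxelIndices)
  flat <- matrix(volumes, prod(dims[1:3]), T)
  lin <- 1L + mask@voxelIndices[, 1] +
    dims[1] * (mask@voxelIndices[, 2] + dims[2] * mask@voxelIndices[, 3])
  new("RoiTimeSeries", data = t(flat[lin, , drop = FALSE]),
      trSec = trSec, sessionId = sessionId, subjectId = subjectId)
}
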