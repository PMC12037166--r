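#' Build a single-session GLM design matrix
#'
#' One column per condition present in the events (the block boxcar sampled
#' at the TR and convolved with the canonical HRF, truncated to the run),
#' plus DCT drift regressors (cutoff 128 s by default) and an intercept.
#' Onsets are interpreted in seconds from the start of the supplied run; if
#' initial volumes were discarded, pass events re-referenced accordingly or
#' use `nDiscarded` to shift them.
#'
#' @param events a [BlockEvents-class].
#' @param T number of volumes the design must cover.
#' @param trSec repetition time in seconds.
#' @param hpCutoffSec drift-basis cutoff period (default 128 s).
#' @param nDiscarded volumes removed from the start of the run; onsets are
#'   shifted by `-nDiscarded * trSec` (default 0).
#' @return a list with `matrix` (T x P, full column rank), `columnNames` and
#'   `trSec`.
#' @export
buildDesign <- function(events, T, trSec, hpCutoffSec = 128, nDiscarded = 0L) {
  ev <- events@events
  ev$onset <- ev$onset - nDiscarded * trSec
  conditions <- intersect(c("task", "replay"), unique(ev$trial_type))
  cols <- lapply(conditions, function(cd) conditionRegressor(ev, cd, T, trSec))
  K <- dctK(T, trSec, hpCutoffSec)
  X <- cbind(do.call(cbind, cols), dctBasis(T, K), 1)
  colnames(X) <- c(conditions,
                   if (K > 0) sprintf("drift%02d", seq_len(K)),
                   "intercept")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  list(matrix = X, columnNames = colnames(X), trSec = trSec)
}

#' Fit an OLS contrast per voxel
#'
#' Ordinary least squares per voxel with a t-statistic for the contrast
#' `c' beta`: `t = c' betahat / sqrt(sigma2 * c' (X'X)^-1 c)` with
#' `df = T - rank(X)`. No autocorrelation prewhitening is applied; this is a
#' sanity-check fit, not a full first-level analysis.
#'
#' @param ts a [RoiTimeSeries-class] with T rows matching the design.
#' @param design output of [buildDesign()].
#' @param contrast numeric weight vector, either length P or a named vector
#'   over a subset of design columns (others 0).
#' @return a list with per-voxel `t`, `beta` (contrast estimate), `df`, and
#'   the residual variance `sigma2`.
#' @export
fitContrast <- function(ts, design, contrast) {
  X <- design$matrix
  if (nrow(X) != nrow(ts@data))
    stop(sprintf("design has %d rows but the series has %d volumes",
                 nrow(X), nrow(ts@data)))
  P <- ncol(X)
  if (!is.null(names(contrast))) {
    cvec <- numeric(P)
    miss <- setdiff(names(contrast), colnames(X))
    if (length(miss))
      stop("contrast names not in design: ", paste(miss, collapse = ", "))
    cvec[match(names(contrast), colnames(X))] <- contrast
  } else {
    if (length(contrast) != P)
      stop(sprintf("contrast length %d != %d design columns",
                   length(contrast), P))
    cvec <- contrast
  }
  qrX <- qr(X)
  if (qrX$rank < P) stop("singular design: X'X is not invertible")
  beta <- qr.coef(qrX, ts@data)
  res <- qr.resid(qrX, ts@data)
  df <- nrow(X) - P
  sigma2 <- colSums(res^2) / df
  xtxInv <- chol2inv(qr.R(qrX))
  cvar <- drop(t(cvec) %*% xtxInv %*% cvec)
  cb <- drop(crossprod(cvec, beta))
  se <- sqrt(sigma2 * cvar)
  t <- ifelse(se == 0, ifelse(cb == 0, 0, sign(cb) * Inf), cb / se)
  list(t = t, beta = cb, df = df, sigma2 = sigma2)
}
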