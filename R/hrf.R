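#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF — the difference of two gamma densities with
#' peak delay 6 s, undershoot delay 16 s, unit dispersions and a
#' peak-to-undershoot ratio of 6 — at the repetition time, over a 32 s
#' support, and rescales the kernel to a peak value of 1.
#'
#' @param trSec sampling interval (repetition time) in seconds; must be > 0.
#' @param lengthSec kernel support in seconds (default 32).
#' @return numeric kernel sampled at `t = 0, trSec, 2*trSec, ...` up to
#'   `lengthSec`, with `max(kernel) == 1`.
#' @examples
#' h <- canonicalHrf(3)
#' length(h)            # 11 samples: t = 0..30 s
#' which.max(h)         # peak at t = 6 s (third sample)
#' @export
canonicalHrf <- function(trSec, lengthSec = 32) {
  if (!is.numeric(trSec) || length(trSec) != 1L || trSec <= 0)
    stop("trSec must be a single positive number")
  t <- seq(0, lengthSec, by = trSec)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}
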