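## internal helpers

## Evaluate expr with a locally seeded RNG, restoring global RNG state after.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-unit seed derived from a master seed; stays < 2^31.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

## Discrete convolution of a signal with a kernel, truncated to the signal
## length ("full" convolution, causal kernel starting at lag 0).
convTrunc <- function(signal, kernel) {
  n <- length(signal)
  out <- convolve(c(signal, numeric(length(kernel) - 1)),
                  rev(kernel), type = "open")
  out[seq_len(n)]
}

## DCT-II drift basis: K columns cos(pi * k * (2t + 1) / (2T)), t = 0..T-1.
dctBasis <- function(T, K) {
  if (K < 1L) return(matrix(numeric(0), T, 0))
  t <- 0:(T - 1)
  vapply(seq_len(K),
         function(k) cos(pi * k * (2 * t + 1) / (2 * T)),
         numeric(T))
}

## Number of DCT drift regressors for a run of T volumes at trSec with the
## given cutoff period.
dctK <- function(T, trSec, cutoffSec) as.integer(floor(2 * T * trSec / cutoffSec))
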