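# Shared fixtures: small, fast configurations; all data generated in code.

# Small ROI for unit tests; keeps the full session/block structure.
smallConfig <- function(...) {
  args <- list(...)
  defaults <- list(nVoxels = 20)
  do.call(simConfig, utils::modifyList(defaults, args))
}

# A raw RoiTimeSeries from a plain matrix.
rawSeries <- function(data, trSec = 3, sessionId = "s1", flags = character()) {
  new("RoiTimeSeries", data = data, trSec = trSec, sessionId = sessionId,
      flags = flags)
}

# A fully preprocessed series from one simulated task session.
preppedTaskSession <- function(cfg, truth, sessionIndex = 1L, seed = 1L) {
  ev <- makeBlockEvents(cfg, sessionIndex)
  list(ts = preprocessSession(simulateTaskSession(cfg, truth, ev, seed)),
       events = ev)
}

# Labelled SampleSet spanning several sessions of one simulated subject.
trainingSamples <- function(cfg, truth, sessions = 1:3, seedBase = 10L) {
  sets <- lapply(sessions, function(k) {
    s <- preppedTaskSession(cfg, truth, k, seedBase + k)
    epochBlocks(s$ts, s$events)
  })
  combineSamples(sets)
}

# Minimal SampleSet built directly from a feature matrix.
sampleSetFromMatrix <- function(x, labels, windowLen = 1L,
                                sessionId = rep("s1", nrow(x))) {
  new("SampleSet", features = x, labels = labels, sessionId = sessionId,
      startVolume = rep(0L, nrow(x)), windowLen = as.integer(windowLen),
      nVoxels = as.integer(ncol(x) / windowLen))
}
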