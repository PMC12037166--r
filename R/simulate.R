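#' Construct a simulation configuration
#'
#' Returns a [SimConfig-class] holding the design constants of the emulated
#' experiment. The defaults reproduce the study design: four task sessions of
#' 10 task + 10 replay blocks (12 s each, 6 s fixation gaps, 9 s initial
#' fixation), 174 task-session and 122 rest-session volumes at TR 3 s with
#' the first three volumes discarded, and a 6 min rest run before and after
#' the first three task sessions.
#'
#' @param ... named overrides of [SimConfig-class] slots, e.g.
#'   `nVoxels = 60`, `patternAmplitude = 0.8`, `nReactEventsPost = 12`.
#' @return a validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nVoxels = 50, nReactEventsPost = 12)
#' @export
simConfig <- function(...) {
  args <- list(...)
  proto <- new("SimConfig")
  intSlots <- c("nVoxels", "nTaskSessions", "blocksPerCondition", "taskScans",
                "restScans", "discardVolumes", "nReactEventsPre",
                "nReactEventsPost")
  for (nm in names(args)) {
    if (!nm %in% slotNames(proto))
      stop("unknown SimConfig field: ", nm)
    val <- args[[nm]]
    if (nm %in% intSlots) val <- as.integer(val)
    slot(proto, nm) <- val
  }
  validObject(proto)
  proto
}

#' Draw the planted condition patterns for one subject
#'
#' Generates unit-norm task and replay multivoxel patterns with a controlled
#' correlation (default 0: the replay pattern is orthogonalised against the
#' task pattern).
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed; the result is a pure function of it.
#' @return a [GroundTruth-class].
#' @export
makeGroundTruth <- function(config, seed) {
  withSeed(seed, {
    V <- config@nVoxels
    z1 <- stats::rnorm(V)
    z2 <- stats::rnorm(V)
    p1 <- z1 / sqrt(sum(z1^2))
    orth <- z2 - sum(z2 * p1) * p1
    orth <- orth / sqrt(sum(orth^2))
    rho <- config@patternCorrelation
    p2 <- rho * p1 + sqrt(1 - rho^2) * orth
    p2 <- p2 / sqrt(sum(p2^2))
    new("GroundTruth", patternTask = p1, patternReplay = p2,
        patternCorrelation = rho)
  })
}

#' Build the block-event table for one task session
#'
#' Lays out `blocksPerCondition` alternating task/replay blocks of
#' `blockDurationSec` separated by `interBlockGapSec` of fixation, after an
#' initial fixation of `initialFixationSec`. Onsets are in seconds from run
#' start (before volume discarding) and are integer multiples of the TR.
#'
#' @param config a [SimConfig-class].
#' @param sessionIndex 1-based task-session number (used for the label).
#' @return a [BlockEvents-class] with `2 * blocksPerCondition` rows.
#' @examples
#' ev <- makeBlockEvents(simConfig(), 1)
#' head(eventTable(ev))   # first task block at 9 s, first replay at 27 s
#' @export
makeBlockEvents <- function(config, sessionIndex = 1L) {
  tr <- config@trSec
  dur <- config@blockDurationSec
  gap <- config@interBlockGapSec
  init <- config@initialFixationSec
  nB <- 2L * config@blocksPerCondition
  if (init %% tr != 0 || (dur + gap) %% tr != 0)
    stop("initialFixationSec and blockDurationSec + interBlockGapSec must be ",
         "integer multiples of trSec so that block onsets fall on volumes")
  onsets <- init + (seq_len(nB) - 1) * (dur + gap)
  runSec <- config@taskScans * tr
  if (onsets[nB] + dur > runSec)
    stop(sprintf(
      "block design overflows the run: last block ends at %.0f s but the run is %.0f s (taskScans * trSec)",
      onsets[nB] + dur, runSec))
  ev <- data.frame(
    onset = onsets,
    duration = dur,
    trial_type = rep(c("task", "replay"), config@blocksPerCondition),
    stringsAsFactors = FALSE
  )
  new("BlockEvents", events = ev, sessionId = sprintf("task%02d", sessionIndex))
}

## Boxcar for one condition sampled at volume times, convolved with the
## canonical HRF and truncated to T volumes.
conditionRegressor <- function(events, condition, T, trSec) {
  tVol <- (0:(T - 1)) * trSec
  box <- numeric(T)
  sel <- events[events$trial_type == condition, , drop = FALSE]
  for (i in seq_len(nrow(sel)))
    box[tVol >= sel$onset[i] & tVol < sel$onset[i] + sel$duration[i]] <- 1
  convTrunc(box, canonicalHrf(trSec))
}

## AR(1) noise matrix: innovations N(0, noiseSd), recursion per voxel.
ar1Noise <- function(T, V, noiseSd, ar1) {
  n <- matrix(stats::rnorm(T * V, sd = noiseSd), T, V)
  if (ar1 != 0 && T > 1)
    for (t in 2:T) n[t, ] <- n[t, ] + ar1 * n[t - 1, ]
  n
}

## Shared low-frequency nuisance: cosine drift plus a centred linear trend.
sharedDrift <- function(T, trSec, amplitude, periodSec, linearAmplitude) {
  t <- (0:(T - 1)) * trSec
  drift <- amplitude * cos(2 * pi * t / periodSec)
  if (T > 1)
    drift <- drift + linearAmplitude * (2 * (0:(T - 1)) / (T - 1) - 1)
  drift
}

#' Simulate one task session
#'
#' Forward model: each condition's planted multivoxel pattern is modulated by
#' its HRF-convolved block boxcar and scaled by `patternAmplitude`; per-voxel
#' AR(1) noise and a shared cosine drift plus linear trend are added. The
#' returned series has `taskScans` volumes (nothing discarded yet).
#'
#' @param config a [SimConfig-class].
#' @param truth a [GroundTruth-class] (see [makeGroundTruth()]).
#' @param events a [BlockEvents-class] for this session.
#' @param seed integer seed.
#' @param subjectId subject label stored in the result.
#' @return a raw [RoiTimeSeries-class].
#' @export
simulateTaskSession <- function(config, truth, events, seed,
                                subjectId = "sim") {
  validObject(events)
  T <- config@taskScans
  V <- config@nVoxels
  ev <- events@events
  regTask <- conditionRegressor(ev, "task", T, config@trSec)
  regReplay <- conditionRegressor(ev, "replay", T, config@trSec)
  signal <- config@patternAmplitude *
    (outer(regTask, truth@patternTask) + outer(regReplay, truth@patternReplay))
  noise <- withSeed(seed, ar1Noise(T, V, config@noiseSd, config@ar1Coef))
  drift <- sharedDrift(T, config@trSec, config@driftAmplitude,
                       config@driftPeriodSec, config@linearTrendAmplitude)
  new("RoiTimeSeries", data = signal + noise + drift,
      trSec = config@trSec, sessionId = events@sessionId,
      subjectId = subjectId)
}

## Draw n non-overlapping event onsets (in retained-volume indices), uniform
## over all feasible non-overlapping configurations, via the stars-and-bars
## bijection with sorted distinct draws.
drawEventOnsets <- function(nRetained, nEvents, eventVolumes) {
  if (nEvents == 0L) return(integer())
  K <- nRetained - nEvents * eventVolumes
  if (K < 0)
    stop(sprintf(
      "cannot place %d non-overlapping events of %d volumes in %d retained volumes",
      nEvents, eventVolumes, nRetained))
  y <- sort(sample.int(K + nEvents, nEvents) - 1L)
  x <- y - (seq_len(nEvents) - 1L)
  as.integer(x + (seq_len(nEvents) - 1L) * eventVolumes)
}

## Fraction (percent) of sliding windows (length windowLen, step 1) over
## nRetained volumes that overlap any planted event.
plantedFraction <- function(onsets, nRetained, eventVolumes, windowLen = 4L) {
  nWin <- nRetained - windowLen + 1L
  if (nWin < 1L) return(0)
  starts <- 0:(nWin - 1L)
  hit <- rep(FALSE, nWin)
  for (o in onsets)
    hit <- hit | (starts <= o + eventVolumes - 1L & starts + windowLen - 1L >= o)
  100 * mean(hit)
}

#' Simulate one resting-state session with planted reactivation events
#'
#' The baseline is AR(1) noise plus the shared drift. Each planted event
#' re-inserts the task pattern for `reactEventDurationSec`, passed through
#' the same HRF forward model as the task blocks, at a uniformly drawn
#' non-overlapping onset within the retained volumes (events start at or
#' after the discard window so they survive preprocessing).
#'
#' @param config a [SimConfig-class].
#' @param truth a [GroundTruth-class].
#' @param nEvents number of planted events.
#' @param seed integer seed.
#' @param sessionId,subjectId labels stored in the result.
#' @return a list with elements `ts` (raw [RoiTimeSeries-class] of
#'   `restScans` volumes), `onsets` (0-based retained-volume event onsets)
#'   and `trueFraction` (percentage of length-4, step-1 windows over the
#'   retained run that overlap any event).
#' @export
simulateRestSession <- function(config, truth, nEvents, seed,
                                sessionId = "rest", subjectId = "sim") {
  T <- config@restScans
  V <- config@nVoxels
  nRet <- T - config@discardVolumes
  evVol <- as.integer(round(config@reactEventDurationSec / config@trSec))
  if (nEvents * evVol > nRet)
    stop(sprintf(
      "infeasible design: %d events of %d volumes exceed the %d retained rest volumes",
      nEvents, evVol, nRet))
  withSeed(seed, {
    onsets <- drawEventOnsets(nRet, as.integer(nEvents), evVol)
    data <- ar1Noise(T, V, config@noiseSd, config@ar1Coef) +
      sharedDrift(T, config@trSec, config@driftAmplitude,
                  config@driftPeriodSec, config@linearTrendAmplitude)
    hrf <- canonicalHrf(config@trSec)
    for (o in onsets) {
      box <- numeric(T)
      abs0 <- o + config@discardVolumes      # absolute volume index
      box[(abs0 + 1):min(T, abs0 + evVol)] <- 1
      data <- data + config@patternAmplitude *
        outer(convTrunc(box, hrf), truth@patternTask)
    }
    list(
      ts = new("RoiTimeSeries", data = data, trSec = config@trSec,
               sessionId = sessionId, subjectId = subjectId),
      onsets = onsets,
      trueFraction = plantedFraction(onsets, nRet, evVol)
    )
  })
}

#' Simulate per-session tracking error for one subject
#'
#' Sessions 1-3 are drawn around the subject's baseline error with a fixed
#' learning decrement per session; the session-4 error is additionally
#' reduced by `behaviorCoupling` error units per percentage point of true
#' reactivation-fraction increase, plus Gaussian noise. All errors are
#' clipped positive. With zero noise and unit coupling the behavioural
#' improvement ([behaviorImprovement()]) exceeds the learning-only
#' improvement (`2 * learningDecrement`) by exactly the true fraction
#' increase.
#'
#' @param config a [SimConfig-class] (fields `baselineError`,
#'   `learningDecrement`, `behaviorCoupling`, `behaviorNoiseSd`).
#' @param trueFractionIncrease post-minus-pre true reactivation fraction, in
#'   percentage points.
#' @param seed integer seed.
#' @return numeric length-4 vector of positive tracking errors.
#' @export
simulateBehavior <- function(config, trueFractionIncrease, seed) {
  withSeed(seed, {
    b <- config@baselineError
    d <- config@learningDecrement
    e <- numeric(4)
    e[1:3] <- b - d * (0:2) + stats::rnorm(3, sd = config@behaviorNoiseSd)
    e[4] <- b - 3 * d - config@behaviorCoupling * trueFractionIncrease +
      stats::rnorm(1, sd = config@behaviorNoiseSd)
    pmax(e, .Machine$double.eps)
  })
}

#' Coupling slope achieving a target population correlation
#'
#' For the linear-Gaussian behaviour model, the population correlation
#' between the true fraction increase and the behavioural improvement is
#' `R = c * s / sqrt(c^2 s^2 + tau^2)` where `c` is the coupling, `s` the
#' between-subject SD of the true increase and `tau` the SD of the noise in
#' the improvement. This inverts that relation.
#'
#' @param targetR desired population correlation in (-1, 1), nonzero.
#' @param sdIncrease between-subject SD of the true fraction increase
#'   (percentage points).
#' @param noiseSd SD of the noise entering the improvement (error units).
#'   Note the improvement `mean(sessions 1-3) - session 4` carries noise SD
#'   `behaviorNoiseSd * sqrt(1/3 + 1)` when each session has independent
#'   noise `behaviorNoiseSd`.
#' @return coupling slope in error units per percentage point.
#' @export
behaviorCouplingForR <- function(targetR, sdIncrease, noiseSd) {
  if (abs(targetR) >= 1 || targetR == 0)
    stop("targetR must be in (-1, 0) or (0, 1)")
  noiseSd / sdIncrease * targetR / sqrt(1 - targetR^2)
}

#' Simulate a cohort of subjects
#'
#' Each subject gets independent condition patterns, `nTaskSessions` task
#' sessions, a pre-task rest run with `nReactEventsPre` planted events and a
#' post-task rest run with `reactEventsPost` events, plus behaviour coupled
#' to the subject's true reactivation-fraction increase. Per-subject seeds
#' are derived deterministically from the master seed, so the same master
#' seed reproduces the cohort bit-for-bit. Subjects alternate between the
#' right-hand and left-hand groups.
#'
#' @param config a [SimConfig-class].
#' @param nSubjects number of subjects (>= 2).
#' @param reactEventsPost planted post-rest event count: a scalar, or a
#'   vector of length `nSubjects` for per-subject variation. Defaults to
#'   `config@nReactEventsPost`.
#' @param seed master integer seed.
#' @return list of [SyntheticSubject-class].
#' @export
simulateCohort <- function(config, nSubjects, reactEventsPost = NULL,
                           seed = 1L) {
  if (nSubjects < 2L) stop("nSubjects must be >= 2")
  if (is.null(reactEventsPost)) reactEventsPost <- config@nReactEventsPost
  reactEventsPost <- as.integer(rep_len(reactEventsPost, nSubjects))
  groups <- rep_len(c("right-hand", "left-hand"), nSubjects)
  lapply(seq_len(nSubjects), function(i) {
    sid <- sprintf("sub-%02d", i)
    s0 <- deriveSeed(seed, i * 101L)
    truth <- makeGroundTruth(config, s0)
    taskSessions <- lapply(seq_len(config@nTaskSessions), function(k) {
      ev <- makeBlockEvents(config, k)
      list(ts = simulateTaskSession(config, truth, ev,
                                    seed = deriveSeed(s0, k),
                                    subjectId = sid),
           events = ev)
    })
    pre <- simulateRestSession(config, truth, config@nReactEventsPre,
                               seed = deriveSeed(s0, 900L),
                               sessionId = "rest-pre", subjectId = sid)
    post <- simulateRestSession(config, truth, reactEventsPost[i],
                                seed = deriveSeed(s0, 901L),
                                sessionId = "rest-post", subjectId = sid)
    inc <- post$trueFraction - pre$trueFraction
    behavior <- simulateBehavior(config, inc, seed = deriveSeed(s0, 902L))
    new("SyntheticSubject",
        subjectId = sid, group = groups[i],
        taskSessions = taskSessions,
        restPre = pre$ts, restPost = post$ts,
        restEventOnsets = list(pre = pre$onsets, post = post$onsets),
        trueFraction = c(pre = pre$trueFraction, post = post$trueFraction),
        behavior = behavior, truth = truth)
  })
}
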