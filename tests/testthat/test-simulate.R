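test_that("block layout alternates conditions on the documented grid", {
  cfg <- smallConfig()
  ev <- eventTable(makeBlockEvents(cfg, 1))
  expect_equal(nrow(ev), 20L)
  expect_equal(ev$trial_type, rep(c("task", "replay"), 10))
  expect_equal(ev$onset[1], 9)                  # initial fixation
  expect_equal(ev$onset[2], 27)                 # 12 s block + 6 s gap later
  expect_true(all(ev$onset %% cfg@trSec == 0))
  expect_equal(unique(ev$duration), 12)
  expect_equal(diff(ev$onset), rep(18, 19))

  # minimal design: one block per condition, no gap
  cfg1 <- smallConfig(blocksPerCondition = 1, interBlockGapSec = 0,
                      initialFixationSec = 0, taskScans = 30)
  ev1 <- eventTable(makeBlockEvents(cfg1, 1))
  expect_equal(ev1$onset, c(0, 12))
  expect_equal(ev1$trial_type, c("task", "replay"))
})

test_that("a design that does not fit the run is rejected by name", {
  expect_error(simConfig(nVoxels = 5, taskScans = 100),
               "block design")
  cfg <- smallConfig()
  cfg@taskScans <- 120L   # bypass constructor: error surfaces at layout time
  expect_error(makeBlockEvents(cfg, 1), "overflows the run")
})

test_that("planted patterns are unit norm with controlled correlation", {
  cfg <- smallConfig(nVoxels = 100)
  tr <- makeGroundTruth(cfg, 7)
  expect_equal(sqrt(sum(tr@patternTask^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(tr@patternReplay^2)), 1, tolerance = 1e-12)
  expect_equal(sum(tr@patternTask * tr@patternReplay), 0, tolerance = 1e-12)
  trc <- makeGroundTruth(simConfig(nVoxels = 100, patternCorrelation = 0.5), 7)
  expect_equal(sum(trc@patternTask * trc@patternReplay), 0.5, tolerance = 1e-12)
})

test_that("task-session forward model is exact in the noise-free limit", {
  cfg0 <- smallConfig(noiseSd = 0, driftAmplitude = 0,
                      linearTrendAmplitude = 0, patternAmplitude = 0)
  truth <- makeGroundTruth(cfg0, 1)
  ev <- makeBlockEvents(cfg0, 1)
  ts0 <- simulateTaskSession(cfg0, truth, ev, seed = 1)
  expect_true(all(tsData(ts0) == 0))

  cfg <- smallConfig(noiseSd = 0, driftAmplitude = 0,
                     linearTrendAmplitude = 0, patternAmplitude = 1.5)
  ts <- simulateTaskSession(cfg, truth, ev, seed = 1)
  # projecting onto the task pattern recovers the HRF-convolved task boxcar
  proj <- drop(tsData(ts) %*% truth@patternTask)
  T <- cfg@taskScans
  tVol <- (0:(T - 1)) * cfg@trSec
  box <- numeric(T)
  evt <- eventTable(ev)
  for (i in which(evt$trial_type == "task"))
    box[tVol >= evt$onset[i] & tVol < evt$onset[i] + evt$duration[i]] <- 1
  # oracle: direct convolution sum reg[n] = sum_k h[k] * box[n - k + 1]
  h <- canonicalHrf(cfg@trSec)
  reg <- vapply(seq_len(T), function(n) {
    k <- seq_len(min(n, length(h)))
    sum(h[k] * box[n - k + 1])
  }, numeric(1))
  expect_lt(max(abs(proj - 1.5 * reg)), 1e-10)
})

test_that("simulation is a pure function of the seed", {
  cfg <- smallConfig()
  truth <- makeGroundTruth(cfg, 3)
  ev <- makeBlockEvents(cfg, 1)
  a <- simulateTaskSession(cfg, truth, ev, seed = 5)
  b <- simulateTaskSession(cfg, truth, ev, seed = 5)
  c <- simulateTaskSession(cfg, truth, ev, seed = 6)
  expect_identical(tsData(a), tsData(b))
  expect_false(identical(tsData(a), tsData(c)))

  r1 <- simulateRestSession(cfg, truth, 3, seed = 5)
  r2 <- simulateRestSession(cfg, truth, 3, seed = 5)
  expect_identical(tsData(r1$ts), tsData(r2$ts))
  expect_identical(r1$onsets, r2$onsets)

  co1 <- simulateCohort(cfg, 3, reactEventsPost = 2, seed = 11)
  co2 <- simulateCohort(cfg, 3, reactEventsPost = 2, seed = 11)
  expect_identical(tsData(co1[[2]]@restPost), tsData(co2[[2]]@restPost))
  expect_identical(co1[[3]]@behavior, co2[[3]]@behavior)
})

test_that("rest events are non-overlapping, in range, with exact bookkeeping", {
  cfg <- smallConfig()
  truth <- makeGroundTruth(cfg, 2)
  r0 <- simulateRestSession(cfg, truth, 0, seed = 1)
  expect_identical(r0$onsets, integer())
  expect_equal(r0$trueFraction, 0)

  nRet <- cfg@restScans - cfg@discardVolumes
  evVol <- 4L
  # one interior event spans 4 volumes -> 7 overlapping windows (4 + 4 - 1)
  r1 <- simulateRestSession(cfg, truth, 1, seed = 42)
  o <- r1$onsets
  if (o >= 3 && o + evVol - 1 <= nRet - 4) {
    expect_equal(r1$trueFraction, 100 * 7 / (nRet - 4 + 1))
  }

  # exhaustive overlap check across 1000 replicate draws
  for (s in 1:1000) {
    on <- withr::with_seed(s, restMVPA:::drawEventOnsets(nRet, 10L, evVol))
    expect_length(on, 10L)
    expect_true(all(on >= 0 & on + evVol <= nRet))
    expect_true(all(diff(sort(on)) >= evVol))
  }

  # bookkeeping equals brute-force window enumeration
  for (s in 1:25) {
    r <- simulateRestSession(cfg, truth, 6, seed = s)
    starts <- 0:(nRet - 4)
    brute <- vapply(starts, function(w) {
      winVols <- w:(w + 3)
      any(vapply(r$onsets, function(o) any(winVols %in% (o:(o + evVol - 1))),
                 logical(1)))
    }, logical(1))
    expect_equal(r$trueFraction, 100 * mean(brute))
  }

  expect_error(simulateRestSession(cfg, truth, 40, seed = 1), "infeasible")
})

test_that("behaviour couples improvement to the true fraction increase", {
  # zero noise, unit coupling: improvement - learning improvement == increase
  cfg <- smallConfig(behaviorNoiseSd = 0, behaviorCoupling = 1)
  e <- simulateBehavior(cfg, trueFractionIncrease = 7.5, seed = 1)
  expect_equal(behaviorImprovement(e) - 2 * cfg@learningDecrement, 7.5)

  # zero coupling: improvement is independent of the increase
  cfg0 <- smallConfig(behaviorCoupling = 0, behaviorNoiseSd = 2)
  inc <- seq(0, 30, length.out = 200)
  imp <- vapply(seq_along(inc), function(i)
    behaviorImprovement(simulateBehavior(cfg0, inc[i], seed = i)), numeric(1))
  expect_lt(abs(cor(inc, imp)), 0.15)

  # coupling/noise chosen for population R = 0.6: sample R close at n = 200
  sdInc <- 5
  noiseImp <- 3 * sqrt(4 / 3)           # improvement-level noise SD
  cfgR <- smallConfig(behaviorCoupling = behaviorCouplingForR(0.6, sdInc, noiseImp),
                      behaviorNoiseSd = 3)
  incR <- withr::with_seed(99, rnorm(200, 15, sdInc))
  impR <- vapply(seq_along(incR), function(i)
    behaviorImprovement(simulateBehavior(cfgR, incR[i], seed = 3000 + i)),
    numeric(1))
  expect_lt(abs(cor(incR, impR) - 0.6), 0.15)
})

test_that("cohort subjects are independent with per-subject structure", {
  cfg <- smallConfig()
  subs <- simulateCohort(cfg, 4, reactEventsPost = 2, seed = 13)
  expect_length(subs, 4L)
  expect_equal(vapply(subs, function(s) s@group, character(1)),
               rep(c("right-hand", "left-hand"), 2))
  for (s in subs) {
    expect_length(s@taskSessions, cfg@nTaskSessions)
    expect_equal(nVolumes(s@taskSessions[[1]]$ts), cfg@taskScans)
    expect_length(s@behavior, 4L)
    expect_true(all(s@behavior > 0))
    expect_length(s@restEventOnsets$post, 2L)
  }
  # noise series of different subjects are mutually uncorrelated: with the
  # (subject-shared deterministic) drift disabled, the mean absolute
  # voxelwise correlation stays near the null expectation
  # E|r| = sqrt(2/pi)/sqrt(T-3) ~ 0.06 at T = 174
  cfgN <- smallConfig(driftAmplitude = 0, linearTrendAmplitude = 0)
  subsN <- simulateCohort(cfgN, 2, reactEventsPost = 0, seed = 17)
  v1 <- tsData(subsN[[1]]@taskSessions[[1]]$ts)
  v2 <- tsData(subsN[[2]]@taskSessions[[1]]$ts)
  expect_lt(mean(abs(diag(cor(v1, v2)))), 0.12)
  # per-subject event counts can vary
  subsVar <- simulateCohort(cfg, 3, reactEventsPost = c(0, 3, 6), seed = 1)
  expect_equal(vapply(subsVar, function(s) length(s@restEventOnsets$post),
                      integer(1)), c(0L, 3L, 6L))
})
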