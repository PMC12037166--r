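test_that("templates are the class means, verified against a direct oracle", {
  cfg <- smallConfig(nVoxels = 15)
  truth <- makeGroundTruth(cfg, 4)
  s <- trainingSamples(cfg, truth)
  tpl <- buildTemplates(s)
  expect_equal(tpl@nSourceBlocks, c(task = 30L, nontask = 30L))
  # brute-force column means
  oracleTask <- apply(s@features[s@labels == "task", ], 2, mean)
  oracleNon <- apply(s@features[s@labels == "replay", ], 2, mean)
  expect_lt(max(abs(tpl@taskTemplate - oracleTask)), 1e-12)
  expect_lt(max(abs(tpl@nontaskTemplate - oracleNon)), 1e-12)

  # one sample per class: templates equal the samples; mean of {v, -v} is zero
  v <- rnorm(8)
  one <- sampleSetFromMatrix(rbind(v, -v), c("task", "replay"), windowLen = 2L)
  tpl1 <- buildTemplates(one)
  expect_equal(tpl1@taskTemplate, v, ignore_attr = TRUE)
  expect_equal(tpl1@nontaskTemplate, -v, ignore_attr = TRUE)
  both <- sampleSetFromMatrix(rbind(v, -v, v, -v),
                              c("task", "task", "replay", "replay"),
                              windowLen = 2L)
  expect_equal(max(abs(buildTemplates(both)@taskTemplate)), 0)
  expect_error(buildTemplates(one[1]), "both")
})

test_that("nearest-template labels match brute force and the closed form", {
  set.seed(31)
  d <- 24L
  tpl <- new("TemplatePair",
             taskTemplate = rnorm(d), nontaskTemplate = rnorm(d),
             nSourceBlocks = c(task = 5L, nontask = 5L),
             windowLen = 4L, nVoxels = 6L)
  x <- matrix(rnorm(1000 * d), 1000, d)
  w <- sampleSetFromMatrix(x, rep("unknown", 1000), windowLen = 4L)
  got <- classifyByDistance(w, tpl)
  # oracle 1: explicit per-window distance loop
  brute <- apply(x, 1, function(row) {
    dt <- sqrt(sum((row - tpl@taskTemplate)^2))
    dn <- sqrt(sum((row - tpl@nontaskTemplate)^2))
    if (dt < dn) "task" else "nontask"
  })
  expect_identical(got, unname(brute))
  # oracle 2: closed-form linear rule
  wvec <- tpl@taskTemplate - tpl@nontaskTemplate
  thr <- (sum(tpl@taskTemplate^2) - sum(tpl@nontaskTemplate^2)) / 2
  linear <- ifelse(drop(x %*% wvec) - thr > 1e-10, "task",
                   ifelse(drop(x %*% wvec) - thr < -1e-10, "nontask", NA))
  ok <- !is.na(linear)
  expect_identical(got[ok], linear[ok])
})

test_that("ties and exact template matches follow the documented rules", {
  tpl <- new("TemplatePair", taskTemplate = c(1, 0), nontaskTemplate = c(-1, 0),
             nSourceBlocks = c(task = 1L, nontask = 1L),
             windowLen = 1L, nVoxels = 2L)
  w <- sampleSetFromMatrix(rbind(c(1, 0), c(0, 3), c(-1, 0)),
                           rep("unknown", 3), windowLen = 1L)
  expect_equal(classifyByDistance(w, tpl), c("task", "nontask", "nontask"))
  lab <- scoreRestRsa(tpl, w)
  expect_equal(lab@method, "rsa")
  expect_equal(taskFraction(lab), 100 / 3)
  wrong <- sampleSetFromMatrix(matrix(0, 1, 4), "unknown", windowLen = 2L)
  expect_error(classifyByDistance(wrong, tpl), "contract mismatch")
})

test_that("labels are invariant under a common orthogonal transform", {
  set.seed(12)
  d <- 12L
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))   # random orthogonal matrix
  tpl <- new("TemplatePair", taskTemplate = rnorm(d),
             nontaskTemplate = rnorm(d),
             nSourceBlocks = c(task = 2L, nontask = 2L),
             windowLen = 3L, nVoxels = 4L)
  x <- matrix(rnorm(200 * d), 200, d)
  w <- sampleSetFromMatrix(x, rep("unknown", 200), windowLen = 3L)
  tplQ <- new("TemplatePair",
              taskTemplate = drop(tpl@taskTemplate %*% Q),
              nontaskTemplate = drop(tpl@nontaskTemplate %*% Q),
              nSourceBlocks = tpl@nSourceBlocks,
              windowLen = 3L, nVoxels = 4L)
  wQ <- sampleSetFromMatrix(x %*% Q, rep("unknown", 200), windowLen = 3L)
  expect_identical(classifyByDistance(w, tpl), classifyByDistance(wQ, tplQ))
})

test_that("symmetric noise is split near-evenly between equal-norm templates", {
  set.seed(55)
  d <- 40L
  t1 <- rnorm(d); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- rnorm(d); t2 <- t2 - sum(t2 * t1) * t1; t2 <- t2 / sqrt(sum(t2^2))
  tpl <- new("TemplatePair", taskTemplate = t1, nontaskTemplate = t2,
             nSourceBlocks = c(task = 1L, nontask = 1L),
             windowLen = 4L, nVoxels = 10L)
  fr <- vapply(1:50, function(i) {
    x <- matrix(rnorm(100 * d), 100, d)
    w <- sampleSetFromMatrix(x, rep("unknown", 100), windowLen = 4L)
    taskFraction(scoreRestRsa(tpl, w))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 50), 3)
})

test_that("planted rest events sit closer to the task template than background", {
  # The detectable RSA signature of planted reactivation: within a rest run,
  # windows overlapping an event are labelled task at a higher rate than
  # background windows. (The run-level fraction itself is pinned by the
  # session mean removal; see the methods vignette.)
  cfg <- smallConfig(nVoxels = 40)
  rates <- t(vapply(1:8, function(i) {
    truth <- makeGroundTruth(cfg, 500 + i)
    s <- trainingSamples(cfg, truth, seedBase = 600L + 10L * i)
    tpl <- buildTemplates(s)
    post <- simulateRestSession(cfg, truth, 8, seed = 800 + i)
    wins <- slidingWindows(preprocessSession(post$ts))
    lab <- windowLabels(scoreRestRsa(tpl, wins))
    evVol <- 4L
    overlap <- vapply(wins@startVolume, function(st)
      any(vapply(post$onsets, function(o)
        st <= o + evVol - 1L && st + 3L >= o, logical(1))), logical(1))
    c(hit = mean(lab[overlap] == "task"), bg = mean(lab[!overlap] == "task"))
  }, numeric(2)))
  expect_gt(mean(rates[, "hit"]), mean(rates[, "bg"]))
  expect_gt(mean(rates[, "hit"]) - mean(rates[, "bg"]), 0.1)
})
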