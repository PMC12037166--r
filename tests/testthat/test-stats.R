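test_that("mixed ANOVA matches the explicit SS oracle on random designs", {
  set.seed(100)
  for (rep in 1:100) {
    n1 <- sample(3:21, 1); n2 <- sample(3:20, 1)
    N <- n1 + n2
    groupOf <- c(rep("right-hand", n1), rep("left-hand", n2))
    pre <- rnorm(N, 50, 8)
    post <- pre + rnorm(N, 2, 6)
    df <- data.frame(
      subject = rep(sprintf("s%02d", 1:N), 2),
      group = rep(groupOf, 2),
      session = rep(c("pre", "post"), each = N),
      value = c(pre, post))
    got <- mixedAnova2x2(df)
    oracle <- mixedAnovaOracle((pre + post) / 2, groupOf, post - pre)
    g <- function(eff) got[got$effect == eff, ]
    expect_equal(g("group")$F, unname(oracle$group["F"]), tolerance = 1e-8)
    expect_equal(g("session")$F, unname(oracle$session["F"]), tolerance = 1e-8)
    expect_equal(g("group:session")$F, unname(oracle$interaction["F"]),
                 tolerance = 1e-8)
    expect_equal(g("group")$pEta2, unname(oracle$group["eta"]),
                 tolerance = 1e-8)
    expect_equal(g("session")$pEta2, unname(oracle$session["eta"]),
                 tolerance = 1e-8)
    expect_equal(g("group:session")$pEta2, unname(oracle$interaction["eta"]),
                 tolerance = 1e-8)
    expect_true(all(got$df1 == 1L))
    expect_true(all(got$df2 == N - 2L))
  }
})

test_that("mixed ANOVA dfs reproduce the cohort design and edge cases", {
  # 21 + 20 subjects -> error df 39
  set.seed(5)
  N <- 41
  groupOf <- c(rep("right-hand", 21), rep("left-hand", 20))
  df <- data.frame(subject = rep(1:N, 2), group = rep(groupOf, 2),
                   session = rep(c("pre", "post"), each = N),
                   value = rnorm(2 * N, 50, 5))
  got <- mixedAnova2x2(df)
  expect_true(all(got$df2 == 39L))
  # all-equal data: all F and eta zero
  dfc <- df; dfc$value <- 7
  gotc <- mixedAnova2x2(dfc)
  expect_true(all(gotc$F == 0))
  expect_true(all(gotc$pEta2 == 0))
  # missing a session for one subject
  expect_error(mixedAnova2x2(df[-1, ]), "one value per session")
  # single-subject group
  dfe <- df; dfe$group <- c("a", rep("b", N - 1), "a", rep("b", N - 1))
  expect_error(mixedAnova2x2(dfe), "at least 2 subjects")
})

test_that("one-group mixed ANOVA reduces to the squared paired t", {
  set.seed(44)
  for (rep in 1:20) {
    n <- sample(4:20, 1)
    pre <- rnorm(n, 50, 6)
    post <- pre + rnorm(n, 1, 4)
    df <- data.frame(subject = rep(1:n, 2), group = "only",
                     session = rep(c("pre", "post"), each = n),
                     value = c(pre, post))
    got <- mixedAnova2x2(df)
    tt <- pairedT(pre, post)
    expect_equal(got$F[got$effect == "session"], tt$t^2, tolerance = 1e-8)
    expect_equal(got$p[got$effect == "session"], tt$p, tolerance = 1e-8)
  }
})

test_that("t statistics match from-scratch formula oracles", {
  set.seed(7)
  for (rep in 1:100) {
    n <- 21
    pre <- rnorm(n, 50, 10); post <- pre + rnorm(n, 3, 5)
    got <- pairedT(pre, post)
    d <- post - pre
    tO <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(got$t, tO, tolerance = 1e-12)
    expect_equal(got$df, n - 1)
    expect_equal(got$p, 2 * pt(-abs(tO), n - 1), tolerance = 1e-12)
    expect_equal(got$d, mean(d) / sd(d), tolerance = 1e-12)

    x <- rnorm(n, 55, 8)
    g1 <- oneSampleT(x, 50)
    t1 <- (mean(x) - 50) / (sd(x) / sqrt(n))
    expect_equal(g1$t, t1, tolerance = 1e-12)
    expect_equal(g1$d, (mean(x) - 50) / sd(x), tolerance = 1e-12)
  }
  # degenerate cases error; antisymmetry and simple d identities hold
  expect_error(pairedT(1:5, 1:5), "zero-variance")
  expect_error(oneSampleT(rep(3, 4), 0), "zero variance")
  a <- c(10, 12, 14, 17); b <- a + c(5, 5.01, 4.99, 5)
  expect_gt(pairedT(a, b)$d, 100)
  expect_equal(pairedT(a, b)$t, -pairedT(b, a)$t)
  x <- c(49, 50, 51)
  expect_equal(oneSampleT(x, mu0 = mean(x) - sd(x))$d, 1, tolerance = 1e-12)
})

test_that("Pearson correlation matches the covariance formula oracle", {
  set.seed(9)
  for (rep in 1:100) {
    x <- rnorm(21); y <- rnorm(21)
    got <- pearsonCorr(x, y)
    rO <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(got$R, rO, tolerance = 1e-12)
    tO <- rO * sqrt(19 / (1 - rO^2))
    expect_equal(got$p, 2 * pt(-abs(tO), 19), tolerance = 1e-10)
  }
  x <- rnorm(10)
  expect_equal(pearsonCorr(x, 2 * x + 1)$R, 1, tolerance = 1e-12)
  y <- rnorm(10); yo <- resid(lm(y ~ x))
  expect_lt(abs(pearsonCorr(x, yo)$R), 1e-10)
  expect_error(pearsonCorr(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearsonCorr(1:2, 2:3), "at least 3")
})

test_that("Bonferroni caps at 1, preserves order, and checks family size", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.5, 4), 1)
  p <- c(0.001, 0.04, 0.2, 0.9)
  expect_equal(order(bonferroni(p, 8)), order(p))
  expect_error(bonferroni(p, 2), "family size")
})

test_that("behavioural improvement is the first-three mean minus session 4", {
  expect_equal(behaviorImprovement(c(40, 35, 30, 25)), 10)
  expect_equal(behaviorImprovement(rep(12, 4)), 0)
  e <- c(40, 35, 30, 25)
  base <- behaviorImprovement(e)
  expect_equal(behaviorImprovement(e - c(0, 0, 0, 3)), base + 3)
  expect_error(behaviorImprovement(c(1, 2, 3)), "length-4")
})

test_that("fraction differences subtract pre from post with antisymmetry", {
  expect_equal(fractionDifference(50, 60), 10)
  expect_equal(fractionDifference(42, 42), 0)
  pre <- c(40, 55); post <- c(52, 50)
  expect_equal(fractionDifference(pre, post), -fractionDifference(post, pre))
  expect_error(fractionDifference(1:2, 1:3), "equal length")
  expect_error(fractionDifference(NA, 5), "missing")
})
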