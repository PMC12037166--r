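#' Post-minus-pre task-fraction difference
#'
#' @param pre,post task fractions (percent) for the pre- and post-task rest
#'   runs; vectors are paired elementwise.
#' @return post minus pre, in percentage points.
#' @export
fractionDifference <- function(pre, post) {
  if (length(pre) != length(post))
    stop("pre and post must have equal length")
  if (anyNA(pre) || anyNA(post)) stop("missing cell in pre/post fractions")
  post - pre
}

#' Two-by-two mixed-design ANOVA
#'
#' Classical sums-of-squares mixed ANOVA with one two-level within-subject
#' factor (`session`) and one two-level between-subject factor (`group`).
#' The between stratum tests `group` against subject-within-group error; the
#' within stratum tests `session` and the interaction against the
#' subject-by-session error. The sums of squares come from [stats::aov()]
#' with an `Error(subject)` stratum; F, p and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`) are computed from them.
#'
#' With a single group the design degenerates to a within-subject ANOVA on
#' `session` alone, whose F equals the squared paired t-statistic.
#'
#' @param data data.frame with columns `subject`, `group` (1 or 2 levels),
#'   `session` (2 levels) and `value`; every subject must have both sessions
#'   and each group at least 2 subjects.
#' @return data.frame with one row per effect (`group`, `session`,
#'   `group:session`; `session` only in the one-group case) and columns
#'   `effect`, `df1`, `df2`, `F`, `p`, `pEta2`.
#' @export
mixedAnova2x2 <- function(data) {
  need <- c("subject", "group", "session", "value")
  if (!all(need %in% names(data)))
    stop("data must have columns subject, group, session, value")
  d <- data.frame(
    subject = factor(data$subject),
    group = factor(data$group),
    session = factor(data$session),
    value = as.numeric(data$value)
  )
  oneGroup <- nlevels(d$group) == 1L
  if (!oneGroup && nlevels(d$group) != 2L)
    stop("group must have 1 or 2 levels")
  if (nlevels(d$session) != 2L) stop("session must have exactly 2 levels")
  counts <- table(d$subject, d$session)
  if (any(counts != 1L))
    stop("every subject must have exactly one value per session")
  perGroup <- table(unique(d[, c("subject", "group")])$group)
  if (any(perGroup < 2L)) stop("each group needs at least 2 subjects")
  fit <- if (oneGroup)
    stats::aov(value ~ session + Error(subject), data = d)
  else
    stats::aov(value ~ group * session + Error(subject), data = d)
  s <- summary(fit)
  with <- as.data.frame(s[["Error: Within"]][[1]])
  rn <- function(tab) trimws(rownames(tab))
  pick <- function(tab, term) {
    i <- match(term, rn(tab))
    c(df = tab$Df[i], ss = tab$`Sum Sq`[i])
  }
  effects <- if (oneGroup) {
    list(session = list(eff = pick(with, "session"),
                        err = pick(with, "Residuals")))
  } else {
    betw <- as.data.frame(s[["Error: subject"]][[1]])
    list(
      group = list(eff = pick(betw, "group"), err = pick(betw, "Residuals")),
      session = list(eff = pick(with, "session"),
                     err = pick(with, "Residuals")),
      `group:session` = list(eff = pick(with, "group:session"),
                             err = pick(with, "Residuals"))
    )
  }
  ## scale-aware zero: constant data leaves only rounding noise in the SS
  ssZero <- 1e-20 * (sum(d$value^2) + 1)
  out <- do.call(rbind, lapply(names(effects), function(nm) {
    e <- effects[[nm]]
    ssE <- e$eff[["ss"]]; dfE <- e$eff[["df"]]
    ssR <- e$err[["ss"]]; dfR <- e$err[["df"]]
    if (ssE < ssZero) ssE <- 0
    Fv <- if (ssE <= 0) 0 else (ssE / dfE) / (ssR / dfR)
    data.frame(
      effect = nm, df1 = dfE, df2 = dfR, F = Fv,
      p = stats::pf(Fv, dfE, dfR, lower.tail = FALSE),
      pEta2 = if (ssE <= 0) 0 else ssE / (ssE + ssR),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Paired t-test with Cohen's d
#'
#' @param pre,post paired numeric vectors of equal length >= 2. The test is
#'   on `post - pre`; `d = mean(diff) / sd(diff)`.
#' @return list with `t`, `df`, `p` (two-sided) and `d`.
#' @export
pairedT <- function(pre, post) {
  if (length(pre) != length(post) || length(pre) < 2L)
    stop("pre and post must be paired vectors of length >= 2")
  diff <- post - pre
  if (stats::sd(diff) == 0)
    stop("zero-variance differences: paired t is undefined")
  ht <- stats::t.test(diff, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, d = mean(diff) / stats::sd(diff))
}

#' One-sample t-test with Cohen's d
#'
#' @param values numeric vector, n >= 2, nonzero variance.
#' @param mu0 null value (e.g. 50 for chance-level accuracy in percent).
#' @return list with `t`, `df`, `p` (two-sided) and
#'   `d = (mean - mu0) / sd`.
#' @export
oneSampleT <- function(values, mu0 = 0) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0)
    stop("zero variance: one-sample t is undefined")
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, d = (mean(values) - mu0) / stats::sd(values))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `R` (sample Pearson correlation), `df` (n - 2) and `p`
#'   (two-sided, via the t transform).
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation is undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ht$estimate), df = unname(ht$parameter), p = ht$p.value)
}

#' Bonferroni correction with explicit family size
#'
#' @param p numeric p-values.
#' @param m family size; must be at least `length(p)`.
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m) {
  if (m < length(p))
    stop(sprintf("family size m = %d is smaller than the %d tests supplied",
                 m, length(p)))
  pmin(1, p * m)
}

#' Behavioural improvement from per-session tracking errors
#'
#' The decrease in tracking error from the average of the first three task
#' sessions to the final (fourth) task session.
#'
#' @param errors numeric length-4 vector of per-session tracking errors.
#' @return `mean(errors[1:3]) - errors[4]`, in error units.
#' @export
behaviorImprovement <- function(errors) {
  if (length(errors) != 4L || anyNA(errors))
    stop("errors must be a complete length-4 vector (one per task session)")
  mean(errors[1:3]) - errors[4]
}
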