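#' Analyse one subject: preprocess, decode, score rest
#'
#' Runs the full single-subject analysis: temporal preprocessing of the
#' training task sessions and both rest runs, block epoching with the
#' hemodynamic label shift, leave-one-session-out decoding accuracy across
#' the training sessions, training of the final decoder on all of them, and
#' sliding-window scoring of the pre- and post-task rest runs with the SVM
#' decoder and/or the nearest-template rule.
#'
#' @param subject a [SyntheticSubject-class] (or any object with the same
#'   slots, e.g. from [readDataset()]).
#' @param trainSessions indices of the task sessions used for training
#'   (default 1:3, the sessions preceding the post-task rest run). A single
#'   session is allowed (per-session classifier); LOSO accuracy is then `NA`.
#' @param windowLen window length in volumes (default 4).
#' @param shiftVolumes hemodynamic label shift in volumes (default 2).
#' @param hpCutoffSec high-pass cutoff period in seconds (default 128).
#' @param svmC SVM penalty (default 1).
#' @param nDiscard initial volumes to discard (default 3).
#' @param methods subset of `c("svm", "rsa")`.
#' @return list with `losoMeanAccuracy`, `losoPerFold`, `fractions` (a
#'   data.frame: subject, group, method, pre, post, diff),
#'   `behaviorImprovement`, and the fitted `model`/`templates`.
#' @export
analyzeSubject <- function(subject, trainSessions = 1:3,
                           windowLen = 4L, shiftVolumes = 2L,
                           hpCutoffSec = 128, svmC = 1, nDiscard = 3L,
                           methods = c("svm", "rsa")) {
  methods <- match.arg(methods, c("svm", "rsa"), several.ok = TRUE)
  trainSets <- lapply(trainSessions, function(k) {
    sess <- subject@taskSessions[[k]]
    ts <- preprocessSession(sess$ts, nDiscard, hpCutoffSec)
    epochBlocks(ts, sess$events, shiftVolumes, windowLen)
  })
  train <- combineSamples(trainSets)
  loso <- if (length(trainSessions) >= 2L) losoAccuracy(train, C = svmC)
          else list(meanAccuracy = NA_real_, perFold = NULL)
  restWin <- lapply(list(pre = subject@restPre, post = subject@restPost),
                    function(ts) slidingWindows(
                      preprocessSession(ts, nDiscard, hpCutoffSec),
                      windowLen, step = 1L))
  model <- NULL
  templates <- NULL
  rows <- list()
  if ("svm" %in% methods) {
    model <- trainDecoder(train, C = svmC)
    rows$svm <- data.frame(
      subject = subject@subjectId, group = subject@group, method = "svm",
      pre = taskFraction(scoreRest(model, restWin$pre)),
      post = taskFraction(scoreRest(model, restWin$post)),
      stringsAsFactors = FALSE)
  }
  if ("rsa" %in% methods) {
    templates <- buildTemplates(train)
    rows$rsa <- data.frame(
      subject = subject@subjectId, group = subject@group, method = "rsa",
      pre = taskFraction(scoreRestRsa(templates, restWin$pre)),
      post = taskFraction(scoreRestRsa(templates, restWin$post)),
      stringsAsFactors = FALSE)
  }
  fractions <- do.call(rbind, rows)
  fractions$diff <- fractionDifference(fractions$pre, fractions$post)
  rownames(fractions) <- NULL
  list(
    losoMeanAccuracy = loso$meanAccuracy,
    losoPerFold = loso$perFold,
    fractions = fractions,
    behaviorImprovement = behaviorImprovement(subject@behavior),
    model = model,
    templates = templates
  )
}

#' Run the full reactivation pipeline on a simulated or stored cohort
#'
#' Simulates (or loads) a cohort, analyses every subject
#' ([analyzeSubject()]), and assembles the cohort-level statistics: the
#' 2x2 mixed-design ANOVA on task fractions (session within, group between)
#' per method, and the Pearson correlation between the post-minus-pre
#' fraction increase and the behavioural improvement. With an `outputDir`
#' the per-subject results, cohort tables, and the configuration + seed are
#' written out; re-running with the same arguments reproduces the CSVs
#' byte-for-byte.
#'
#' @param config a [SimConfig-class] (ignored when `inputDir` is given).
#' @param nSubjects cohort size (default 20).
#' @param reactEventsPost planted post-rest events (scalar or per-subject
#'   vector); default `config@nReactEventsPost`.
#' @param seed master seed for the simulation.
#' @param inputDir optional dataset directory written by [writeDataset()];
#'   when given, data are loaded instead of simulated.
#' @param methods subset of `c("svm", "rsa")`.
#' @param outputDir optional directory for result CSVs and metadata.
#' @param ... further arguments passed to [analyzeSubject()].
#' @return list with `results` (per subject x method data.frame: subject,
#'   group, method, pre, post, diff, behaviorImprovement, losoAccuracy),
#'   `anova` (per method), `correlation` (per method), `subjects`, `config`
#'   and `seed`.
#' @export
runPipeline <- function(config = simConfig(), nSubjects = 20L,
                        reactEventsPost = NULL, seed = 1L,
                        inputDir = NULL, methods = c("svm", "rsa"),
                        outputDir = NULL, ...) {
  subjects <- if (is.null(inputDir))
    simulateCohort(config, nSubjects, reactEventsPost, seed)
  else readDataset(inputDir, trSec = config@trSec)
  perSubject <- lapply(subjects, function(sub) {
    res <- tryCatch(analyzeSubject(sub, methods = methods, ...),
                    error = function(e) stop(sprintf(
                      "analysis stage failed for %s: %s",
                      sub@subjectId, conditionMessage(e)), call. = FALSE))
    df <- res$fractions
    df$behaviorImprovement <- res$behaviorImprovement
    df$losoAccuracy <- res$losoMeanAccuracy
    df
  })
  results <- do.call(rbind, perSubject)
  rownames(results) <- NULL
  anova <- lapply(split(results, results$method), function(df) {
    long <- rbind(
      data.frame(subject = df$subject, group = df$group,
                 session = "pre", value = df$pre),
      data.frame(subject = df$subject, group = df$group,
                 session = "post", value = df$post))
    mixedAnova2x2(long)
  })
  correlation <- lapply(split(results, results$method), function(df) {
    if (stats::sd(df$diff) == 0 || stats::sd(df$behaviorImprovement) == 0)
      return(list(R = NA_real_, df = NA_real_, p = NA_real_))
    pearsonCorr(df$diff, df$behaviorImprovement)
  })
  out <- list(results = results, anova = anova, correlation = correlation,
              subjects = subjects, config = config, seed = seed)
  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(outputDir, "results.csv"),
                     row.names = FALSE)
    anovaTab <- do.call(rbind, lapply(names(anova), function(m)
      cbind(method = m, anova[[m]])))
    utils::write.csv(anovaTab, file.path(outputDir, "anova.csv"),
                     row.names = FALSE)
    cfgList <- lapply(slotNames(config), function(s) slot(config, s))
    names(cfgList) <- slotNames(config)
    jsonlite::write_json(
      list(config = cfgList, seed = seed, nSubjects = length(subjects),
           methods = methods,
           packageVersion = as.character(utils::packageVersion("restMVPA"))),
      file.path(outputDir, "run_metadata.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}
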