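# Independent statistical oracles used by the unit and acceptance suites.

# Explicit SS decomposition for the 2x2 mixed design (one within factor with
# two levels, one between factor). Between stratum: groups vs
# subjects-within-groups; within stratum: the per-subject session
# differences d_i carry session, interaction and error.
mixedAnovaOracle <- function(subjectMeans, groupOf, dPerSubject) {
  groups <- unique(groupOf)
  n <- table(factor(groupOf, levels = groups))
  gMean <- tapply(subjectMeans, groupOf, mean)[groups]
  ssGroup <- sum(2 * n * (gMean - weighted.mean(gMean, n))^2)
  ssSubj <- sum(2 * (subjectMeans - gMean[groupOf])^2)
  dbar <- mean(dPerSubject)
  dbarG <- tapply(dPerSubject, groupOf, mean)[groups]
  N <- length(subjectMeans)
  ssSession <- N * dbar^2 / 2
  ssInter <- sum(n * dbarG^2) / 2 - ssSession
  ssErr <- sum((dPerSubject - dbarG[groupOf])^2) / 2
  dfErr <- N - 2
  list(
    group = c(F = (ssGroup / 1) / (ssSubj / dfErr),
              eta = ssGroup / (ssGroup + ssSubj)),
    session = c(F = (ssSession / 1) / (ssErr / dfErr),
                eta = ssSession / (ssSession + ssErr)),
    interaction = c(F = (ssInter / 1) / (ssErr / dfErr),
                    eta = ssInter / (ssInter + ssErr)),
    dfErr = dfErr
  )
}
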