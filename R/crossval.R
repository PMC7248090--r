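# Workload-matched cross-validation, stress-index assembly, AUC/ACC
# evaluation per stress pair, and the phase-shuffled permutation null.

# Internal engine shared by the measured run and the permutation null.
#
# phaseEval assigns each phase an evaluation label among none / medium /
# high / post; per workload level the fold trains on the (none, high) phase
# pair of that workload with class labels none(0)/high(1), after z-scoring
# (fit on the training rows) and SMOTE balancing, then scores every row with
# the fold's transform. Rows of "post" phases are scored but excluded from
# the pairwise evaluation, mirroring the residual-stress reading of the
# final slot.
#
# `pure` flags rows whose merge window lies entirely within one phase; only
# pure rows are used for fitting and pairwise evaluation, because a window
# straddling a phase boundary mixes the two phases' samples and would let
# the contiguous measured geometry leak class information that no shuffled
# assignment can enjoy. Every row is still scored for the index. Returns
# per-fold scores, models, pairwise AUC/ACC and an audit of the row sets
# used for fitting.
cvEngine <- function(X, lab, phaseEval, pure, pEnter = 0.05, pRemove = 0.10,
                     maxFeatures = 60, k = 5, seed = 1, quiet = FALSE) {
  n <- nrow(X)
  phases <- names(phaseEval)
  workloadOf <- substr(phases, 1, 1)           # L / M / H prefix
  folds <- list()
  for (w in c("L", "M", "H")) {
    ph <- phases[workloadOf == w]
    tr0 <- ph[phaseEval[ph] == "none"]
    tr1 <- ph[phaseEval[ph] == "high"]
    if (length(tr0) < 1 || length(tr1) < 1) next
    folds[[length(folds) + 1L]] <-
      list(workload = w, trainPhases = c(tr0[1], tr1[1]))
  }
  if (!length(folds)) return(NULL)

  scores <- matrix(NA_real_, length(folds), n)
  testMask <- matrix(FALSE, length(folds), n)
  models <- vector("list", length(folds))
  audit <- vector("list", length(folds))
  pairs <- rbind(c("none", "medium"), c("none", "high"), c("medium", "high"))
  ev <- array(NA_real_, c(length(folds), 3, 2),
              dimnames = list(NULL, paste(pairs[, 1], pairs[, 2], sep = "_vs_"),
                              c("auc", "acc")))
  rowEval <- phaseEval[lab$phase]

  for (f in seq_along(folds)) {
    fd <- folds[[f]]
    trainPhaseRows <- which(lab$phase %in% fd$trainPhases)
    trainRows <- trainPhaseRows[pure[trainPhaseRows]]
    testRows <- setdiff(seq_len(n), trainPhaseRows)
    yTrain <- factor(ifelse(phaseEval[lab$phase[trainRows]] == "high",
                            "high", "none"), levels = c("none", "high"))
    zs <- zscoreFitApply(X[trainRows, , drop = FALSE], X)
    bal <- smoteOversample(zs$train, yTrain, k = k, seed = seed + f)
    model <- tryCatch(
      swldaFit(bal$X, factor(bal$y, levels = c("none", "high")),
               pEnter, pRemove, maxFeatures),
      swldaEmptyModel = function(e) {
        if (!quiet)
          warning("fold ", f, ": empty model; falling back to best single feature")
        pv <- vapply(seq_len(ncol(bal$X)), function(j)
          suppressWarnings(stats::t.test(bal$X[bal$y == "high", j],
                                         bal$X[bal$y == "none", j])$p.value),
          numeric(1))
        swldaFit(bal$X[, which.min(pv), drop = FALSE],
                 factor(bal$y, levels = c("none", "high")),
                 pEnter = 0.999, pRemove = 1, maxFeatures = 1)
      })
    sAll <- swldaScore(model, zs$others[[1]])
    scores[f, ] <- sAll
    testMask[f, testRows] <- TRUE
    models[[f]] <- model
    audit[[f]] <- list(workload = fd$workload, trainPhases = fd$trainPhases,
                       trainRows = trainRows, testRows = testRows)
    prob <- swldaProbability(model, sAll)
    evalRows <- testRows[pure[testRows]]
    for (pp in seq_len(nrow(pairs))) {
      a <- pairs[pp, 1]; b <- pairs[pp, 2]
      rows <- evalRows[rowEval[evalRows] %in% c(a, b)]
      isPos <- rowEval[rows] == b
      if (sum(isPos) > 0 && sum(!isPos) > 0) {
        ev[f, pp, "auc"] <- aucRank(sAll[rows], isPos)
        ev[f, pp, "acc"] <- mean((prob[rows] >= 0.5) == isPos)
      }
    }
  }
  list(folds = folds, scores = scores, testMask = testMask, models = models,
       audit = audit, pairEval = ev)
}

# Rows whose merge window lies entirely within the phase named in their label.
pureRowsOf <- function(lab, timeline, window) {
  ph <- phaseTable(timeline)
  idx <- match(lab$phase, ph$label)
  lab$windowStart + window <= ph$end[idx] + 1e-9
}

mergeWindowOf <- function(table) {
  w <- S4Vectors::metadata(table)$window
  if (is.null(w)) 30 else w
}

phaseEvalOf <- function(timeline) {
  ph <- phaseTable(timeline)
  ev <- c("none", "medium", "high", "post")[ph$slot]
  names(ev) <- ph$label
  ev
}

#' Workload-matched cross-validated stress index
#'
#' Runs the three workload-matched folds: each fold trains the SWLDA on the
#' LOW (or MEDIUM, or HIGH) workload phases of the no-stress and high-stress
#' slots with class labels none/high, after z-score normalisation (fitted on
#' the training rows only) and SMOTE balancing of the training rows, then
#' scores every window. Windows that straddle a phase boundary mix the two
#' phases' samples, so they are excluded from fitting and from the pairwise
#' evaluation (they are still scored). The stress index at a time step is the mean
#' discriminant score over the folds in which that step was test data; steps
#' inside a fold's training phases receive the remaining folds' predictions.
#'
#' @param table a [StressFeatureTable-class] for one subject.
#' @param timeline the [ScenarioTimeline-class] the table was labelled from.
#' @param pEnter,pRemove,maxFeatures stepwise parameters, see [swldaFit()].
#' @param k SMOTE neighbour count.
#' @param seed integer seed (SMOTE randomness).
#' @return `list(index = StressIndexSeries, models, scores, testMask,
#'   audit, pairEval)`; `audit` records the training-row sets each fold used
#'   for normalisation, SMOTE and fitting.
#' @export
runCrossValidation <- function(table, timeline, pEnter = 0.05,
                               pRemove = 0.10, maxFeatures = 60, k = 5,
                               seed = 1) {
  stopifnot(is(table, "StressFeatureTable"))
  lab <- windowLabels(table)
  X <- featureMatrix(table)
  phaseEval <- phaseEvalOf(timeline)
  missing <- setdiff(names(phaseEval), unique(lab$phase))
  if (length(missing))
    stop("phase(s) missing from the table: ", paste(missing, collapse = ", "))
  pure <- pureRowsOf(lab, timeline, mergeWindowOf(table))
  res <- cvEngine(X, lab, phaseEval, pure, pEnter, pRemove, maxFeatures,
                  k, seed)
  nf <- colSums(res$testMask)
  ySum <- colSums(res$scores * res$testMask)
  idx <- new("StressIndexSeries", time = lab$windowStart,
             y = ySum / nf, nFolds = as.integer(nf))
  c(list(index = idx), res)
}

#' AUC and ACC per stress pair
#'
#' Pairwise discrimination (AUC, rank formulation with ties counting one
#' half) and classification accuracy (logistic probability thresholded at
#' 0.5) for the none-vs-medium, none-vs-high and medium-vs-high comparisons,
#' evaluated on each fold's test rows and averaged across folds. Windows of
#' the final slot are scored but excluded: the no-stress reference is the
#' first slot only. Because per-fold evaluation and fold-averaged-index
#' evaluation need not agree, the index-level AUC computed from the fold-
#' averaged series is reported alongside.
#'
#' @param cv result of [runCrossValidation()].
#' @param table the [StressFeatureTable-class] the index was computed on.
#' @return `list(perFold, averaged, indexLevel)`: `perFold` the fold x pair
#'   array, `averaged` a `data.frame(pair, auc, acc)` of fold means,
#'   `indexLevel` pairwise AUC of the fold-averaged index.
#' @export
evaluateStress <- function(cv, table) {
  lab <- windowLabels(table)
  ev <- cv$pairEval
  avg <- data.frame(pair = dimnames(ev)[[2]],
                    auc = apply(ev[, , "auc", drop = FALSE], 2, mean, na.rm = TRUE),
                    acc = apply(ev[, , "acc", drop = FALSE], 2, mean, na.rm = TRUE))
  y <- indexValues(cv$index)
  stressOf <- c("none", "medium", "high", "post")[lab$slot]
  pairs <- rbind(c("none", "medium"), c("none", "high"), c("medium", "high"))
  idxAuc <- vapply(seq_len(nrow(pairs)), function(pp) {
    rows <- which(stressOf %in% pairs[pp, ])
    aucRank(y[rows], stressOf[rows] == pairs[pp, 2])
  }, numeric(1))
  list(perFold = ev, averaged = avg,
       indexLevel = data.frame(pair = avg$pair, auc = idxAuc))
}

#' Permutation null for the stress classification
#'
#' Shuffles the stress-condition labels at the phase level: the twelve
#' phase labels (three none, three medium, three high, three post) are
#' randomly reassigned to the phases, the full workload-matched
#' cross-validation (z-score, SMOTE, SWLDA) is re-run under the permuted
#' assignment, and the fold-averaged AUC/ACC per stress pair is recorded.
#' Folds whose workload level lacks a none or high phase under a permutation
#' are skipped. Deterministic given the seed.
#'
#' @param table a [StressFeatureTable-class].
#' @param timeline the session [ScenarioTimeline-class].
#' @param nPerm number of permutations (a warning is issued below 100).
#' @param seed integer seed.
#' @param ... passed to the cross-validation engine.
#' @return `data.frame(perm, pair, auc, acc)` of null values.
#' @export
permutationNull <- function(table, timeline, nPerm = 200, seed = 1, ...) {
  if (nPerm < 100) warning("fewer than 100 permutations: null will be coarse")
  lab <- windowLabels(table)
  X <- featureMatrix(table)
  phaseEval <- phaseEvalOf(timeline)
  pure <- pureRowsOf(lab, timeline, mergeWindowOf(table))
  withSeed(seed, {
    out <- vector("list", nPerm)
    for (b in seq_len(nPerm)) {
      perm <- setNames(sample(unname(phaseEval)), names(phaseEval))
      res <- cvEngine(X, lab, perm, pure, seed = seed + 1000L + b,
                      quiet = TRUE, ...)
      if (is.null(res)) next
      ev <- res$pairEval
      out[[b]] <- data.frame(
        perm = b, pair = dimnames(ev)[[2]],
        auc = apply(ev[, , "auc", drop = FALSE], 2, mean, na.rm = TRUE),
        acc = apply(ev[, , "acc", drop = FALSE], 2, mean, na.rm = TRUE))
    }
    do.call(rbind, out)
  })
}

#' Permutation p-value of a measured statistic
#'
#' `(1 + #{null >= measured}) / (n + 1)`, the add-one permutation p-value.
#'
#' @param measured observed value.
#' @param null vector of null values.
#' @export
permutationP <- function(measured, null) {
  null <- null[is.finite(null)]
  (1 + sum(null >= measured)) / (length(null) + 1)
}
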