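# Feature fusion: merge the three modalities on a common 30-s/0.5-s time
# base, screen features for stress sensitivity across subjects, z-score
# normalisation fitted on training rows only, and SMOTE class balancing.

#' Default merged feature names
#' @param channels EEG feature channels.
#' @param bands band names.
#' @return character vector `psd_<channel>_<band>` in band-major order.
#' @export
featureNames <- function(channels = featureChannels(),
                         bands = c("theta", "alpha", "beta", "gamma")) {
  as.vector(outer(channels, bands, function(c, b) paste("psd", c, b, sep = "_")))
}

# mean over rows i1..i2 of each column, via cumulative sums; NA when empty
cumWindowMean <- function(cum, i1, i2) {
  if (i2 < i1) return(rep(NA_real_, ncol(cum) - 0L))
  (cum[i2 + 1L, ] - cum[i1, ]) / (i2 - i1 + 1L)
}

#' Merge modalities into a windowed feature table
#'
#' For every 30-s window advancing by 0.5 s: EEG band powers are averaged
#' over the clean epochs fully inside the window, SCL (and optionally SCR)
#' over the 5-s electrodermal sub-windows inside it, and LF/HF (optionally
#' mean HR) is taken from the non-overlapping 30-s HRV window covering the
#' window start. Each row is labelled with the slot, phase, workload and
#' stress condition at its start time. Rows for which any modality is
#' missing (e.g. every EEG epoch in the window was artifact-flagged, or the
#' covering HRV window had too few beats) are dropped with a message.
#'
#' With the default 14 channels x 4 bands plus LF/HF and SCL the table has
#' 58 features, and a 3600-s session yields (3600 - 30)/0.5 = 7140 rows
#' before any missingness.
#'
#' @param spectral a [SpectralFeatures-class] with band powers filled in.
#' @param hrv an [HRVWindows-class].
#' @param eda `data.frame(windowStart, scl, scr)` from [windowEda()].
#' @param timeline a [ScenarioTimeline-class].
#' @param window,step merge window and step, seconds.
#' @param channels EEG channels entering the feature set.
#' @param subject subject identifier stored in the labels.
#' @param includeHr,includeScr add mean HR / mean SCR columns (off by
#'   default: they are retained behind these flags for screening studies).
#' @return a [StressFeatureTable-class].
#' @export
mergeFeatures <- function(spectral, hrv, eda, timeline, window = 30,
                          step = 0.5, channels = featureChannels(),
                          subject = "S1", includeHr = FALSE,
                          includeScr = FALSE) {
  stopifnot(is(spectral, "SpectralFeatures"), is(hrv, "HRVWindows"),
            is(timeline, "ScenarioTimeline"))
  bp <- bandPowerArray(spectral)
  if (!length(bp)) stop("band powers missing: run bandPowers() first")
  miss <- setdiff(channels, dimnames(bp)[[2]])
  if (length(miss)) stop("channels absent from spectra: ",
                         paste(miss, collapse = ", "))
  dur <- sessionDuration(timeline)
  starts <- seq(0, by = step, length.out = floor((dur - window) / step))

  bands <- dimnames(bp)[[3]]
  eegMat <- do.call(cbind, lapply(bands, function(b) bp[, channels, b]))
  colnames(eegMat) <- featureNames(channels, bands)
  epStart <- spectral@epochStart
  win_e <- 2                                   # epoch length, s
  cumEeg <- rbind(0, apply(eegMat, 2, cumsum))
  i1 <- findInterval(starts - 1e-9, epStart) + 1L
  i2 <- findInterval(starts + window - win_e + 1e-9, epStart)
  eegRows <- t(vapply(seq_along(starts), function(j)
    cumWindowMean(cumEeg, i1[j], i2[j]), numeric(ncol(eegMat))))
  colnames(eegRows) <- colnames(eegMat)

  edaWin <- eda$windowStart[2] - eda$windowStart[1]
  cumScl <- rbind(0, apply(cbind(scl = eda$scl, scr = eda$scr), 2, cumsum))
  e1 <- findInterval(starts - 1e-9, eda$windowStart) + 1L
  e2 <- findInterval(starts + window - edaWin + 1e-9, eda$windowStart)
  edaRows <- t(vapply(seq_along(starts), function(j)
    cumWindowMean(cumScl, e1[j], e2[j]), numeric(2)))

  hw <- hrvTable(hrv)
  hIdx <- findInterval(starts + 1e-9, hw$windowStart)
  hIdx[hIdx < 1L] <- NA_integer_
  lfhf <- hw$lfhf[hIdx]
  hr <- hw$hrMean[hIdx]

  X <- cbind(eegRows, lf_hf = lfhf, scl = edaRows[, 1])
  if (includeHr) X <- cbind(X, hr = hr)
  if (includeScr) X <- cbind(X, scr = edaRows[, 2])

  ok <- complete.cases(X)
  if (any(!ok))
    message(sum(!ok), " of ", length(ok),
            " windows dropped (missing modality data)")
  labels <- timelineLabels(timeline, starts[ok])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X[ok, , drop = FALSE])),
    colData = S4Vectors::DataFrame(
      windowStart = starts[ok], slot = labels$slot, phase = labels$phase,
      workload = labels$workload, stress = labels$stress, subject = subject))
  S4Vectors::metadata(se)$window <- window
  new("StressFeatureTable", se)
}

#' Feature matrix of a StressFeatureTable (rows = windows)
#' @param table a [StressFeatureTable-class].
#' @export
featureMatrix <- function(table) {
  t(SummarizedExperiment::assay(table, "features"))
}

#' Window labels of a StressFeatureTable
#' @param table a [StressFeatureTable-class].
#' @export
windowLabels <- function(table) {
  as.data.frame(SummarizedExperiment::colData(table))
}

#' Combine per-subject feature tables
#' @param tables list of [StressFeatureTable-class] objects.
#' @export
combineTables <- function(tables) {
  stopifnot(length(tables) >= 1)
  if (length(tables) == 1) return(tables[[1]])
  feats <- rownames(tables[[1]])
  for (tb in tables[-1])
    if (!identical(rownames(tb), feats))
      stop("tables carry different feature sets")
  X <- do.call(cbind, lapply(tables, SummarizedExperiment::assay, "features"))
  cd <- do.call(rbind, lapply(tables, SummarizedExperiment::colData))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = X), colData = cd)
  new("StressFeatureTable", se)
}

#' Screen features for stress sensitivity
#'
#' For every subject and feature, the feature is averaged over the no-stress
#' slot (slot 1) and over the high-stress slot (slot 3); the paired per-
#' subject means are then compared by an exact-distribution Wilcoxon
#' signed-rank test per feature, and features with `p < alpha` are selected.
#'
#' @param tables list of per-subject [StressFeatureTable-class] objects (or
#'   a single combined table carrying several subjects).
#' @param alpha selection level.
#' @return `data.frame(feature, statistic, p, selected)` with attribute
#'   `alpha`.
#' @export
screenFeatures <- function(tables, alpha = 0.05) {
  if (is(tables, "StressFeatureTable")) tables <- list(tables)
  big <- combineTables(tables)
  lab <- windowLabels(big)
  X <- featureMatrix(big)
  subjects <- unique(lab$subject)
  if (length(subjects) < 6)
    stop("screening requires at least 6 subjects")
  slotMean <- function(s, subj)
    colMeans(X[lab$subject == subj & lab$slot == s, , drop = FALSE])
  m1 <- t(vapply(subjects, slotMean, numeric(ncol(X)), s = 1))
  m3 <- t(vapply(subjects, slotMean, numeric(ncol(X)), s = 3))
  res <- lapply(seq_len(ncol(X)), function(j) {
    w <- suppressWarnings(wilcoxonSignedRank(m3[, j], m1[, j]))
    data.frame(feature = colnames(X)[j], statistic = unname(w$statistic),
               p = w$p.value)
  })
  out <- do.call(rbind, res)
  out$selected <- out$p < alpha
  attr(out, "alpha") <- alpha
  out
}

#' Fit and apply z-score normalisation
#'
#' Column means and standard deviations are estimated on the training rows
#' only and applied to the training matrix and any further matrices, keeping
#' test data out of the normalisation fit.
#'
#' @param train numeric training matrix (rows = observations).
#' @param ... further matrices to transform with the training statistics.
#' @return `list(train, others, center, scale)`.
#' @export
zscoreFitApply <- function(train, ...) {
  center <- colMeans(train)
  scale <- apply(train, 2, sd)
  bad <- which(scale < .Machine$double.eps^0.5)
  if (length(bad))
    stop("constant training column(s): ",
         paste(colnames(train)[bad], collapse = ", "))
  tf <- function(m) sweep(sweep(m, 2, center), 2, scale, "/")
  list(train = tf(train), others = lapply(list(...), tf),
       center = center, scale = scale)
}

#' SMOTE oversampling of the minority class
#'
#' Each synthetic sample is `x_i + u (x_nn - x_i)` with `u ~ Uniform(0, 1)`
#' and `x_nn` one of the `k` nearest minority-class neighbours (Euclidean
#' metric) of a randomly chosen minority sample `x_i`. The minority class is
#' grown to the majority size; majority rows are untouched. Deterministic
#' given the seed.
#'
#' @param X numeric matrix (rows = observations).
#' @param y class labels, exactly two classes.
#' @param k number of nearest neighbours.
#' @param seed integer seed.
#' @return `list(X, y, synthetic)` where `synthetic` flags generated rows.
#' @export
smoteOversample <- function(X, y, k = 5, seed = 1) {
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2) stop("exactly two classes required")
  if (tab[1] == tab[2])
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  minClass <- names(tab)[which.min(tab)]
  minIdx <- which(y == minClass)
  m <- length(minIdx)
  if (m <= k) stop("minority class must exceed k = ", k, " samples")
  nNew <- as.integer(max(tab) - m)
  withSeed(seed, {
    Xm <- X[minIdx, , drop = FALSE]
    D <- as.matrix(dist(Xm))
    diag(D) <- Inf
    nn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
    base <- sample.int(m, nNew, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, nNew, replace = TRUE))]
    u <- runif(nNew)
    synth <- Xm[base, , drop = FALSE] +
      u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
    list(X = rbind(X, synth), y = c(y, rep(minClass, nNew)),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nNew)))
  })
}
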