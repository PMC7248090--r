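#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx coef complete.cases cor dist fft lm lm.fit mad median
#'   na.omit pchisq pf pnorm qnorm quantile rbinom rgamma rnorm rpois runif
#'   sd setNames spline splinefun var
#' @importFrom utils head read.csv tail write.csv
NULL

# ---------------------------------------------------------------------------
# Scenario model
# ---------------------------------------------------------------------------

#' ScenarioTimeline: the session plan
#'
#' Describes a simulated control session: four stress slots partitioned into
#' three workload phases each, the stressful events embedded in the medium-
#' and high-stress slots, and the instants at which subjective ratings are
#' collected. All intervals are half-open `[start, end)` in seconds from the
#' session origin.
#'
#' @slot totalDuration session length in seconds.
#' @slot slots `data.frame` with columns `index`, `stress`
#'   (`none`/`medium`/`high`), `start`, `end`.
#' @slot phases `data.frame` with columns `label` (e.g. `LWL1`), `workload`
#'   (`LOW`/`MEDIUM`/`HIGH`), `start`, `end`, `slot`.
#' @slot events `data.frame` with columns `onset`, `duration`, `level`,
#'   `kind`.
#' @slot ratingTimes numeric vector of rating instants in seconds.
#'
#' @seealso [generateTimeline()]
#' @export
setClass("ScenarioTimeline",
  representation(
    totalDuration = "numeric",
    slots = "data.frame",
    phases = "data.frame",
    events = "data.frame",
    ratingTimes = "numeric"
  )
)

setValidity("ScenarioTimeline", function(object) {
  msg <- character()
  ph <- object@phases
  sl <- object@slots
  if (nrow(sl) != 4L) msg <- c(msg, "expected exactly 4 slots")
  if (abs(sum(ph$end - ph$start) - object@totalDuration) > 1e-9)
    msg <- c(msg, "phase durations must sum to totalDuration")
  if (any(ph$start[-1] != ph$end[-nrow(ph)]))
    msg <- c(msg, "phases must be contiguous")
  for (i in seq_len(nrow(sl))) {
    phs <- ph[ph$slot == sl$index[i], ]
    if (nrow(phs) != 3L) msg <- c(msg, "each slot must hold 3 phases")
    if (nrow(phs) && (min(phs$start) != sl$start[i] || max(phs$end) != sl$end[i]))
      msg <- c(msg, "phases must partition their slot")
  }
  ev <- object@events
  if (nrow(ev)) {
    for (j in seq_len(nrow(ev))) {
      pidx <- which(ph$start <= ev$onset[j] & ev$onset[j] < ph$end)
      if (!length(pidx) || ev$onset[j] + ev$duration[j] > ph$end[pidx])
        msg <- c(msg, "events must not cross phase boundaries")
    }
    slotOf <- function(t) sl$index[sl$start <= t & t < sl$end]
    evSlot <- vapply(ev$onset, slotOf, numeric(1))
    if (any(ev$level == "medium" & evSlot != 2) ||
        any(ev$level == "high" & evSlot != 3))
      msg <- c(msg, "medium events belong in SLOT#2, high events in SLOT#3")
  }
  if (length(msg)) msg else TRUE
})

#' MultimodalRecording: synchronised raw signals
#'
#' Raw EEG, ECG and skin-conductance streams sharing a clock origin, plus the
#' one-minute eyes-closed EEG baseline used for individual-alpha-frequency
#' estimation.
#'
#' @slot eeg channels x samples matrix, microvolts; rownames are channel
#'   labels.
#' @slot eegRate,ecgRate,gsrRate sampling rates in Hz.
#' @slot ecg numeric ECG vector (mV scale).
#' @slot gsr numeric skin conductance vector (microsiemens).
#' @slot ocBaseline channels x samples matrix: eyes-closed EEG baseline.
#' @slot t0 shared clock origin in seconds.
#' @export
setClass("MultimodalRecording",
  representation(
    eeg = "matrix", eegRate = "numeric",
    ecg = "numeric", ecgRate = "numeric",
    gsr = "numeric", gsrRate = "numeric",
    ocBaseline = "matrix", t0 = "numeric"
  )
)

setValidity("MultimodalRecording", function(object) {
  msg <- character()
  if (any(c(object@eegRate, object@ecgRate, object@gsrRate) <= 0))
    msg <- c(msg, "sampling rates must be positive")
  labs <- rownames(object@eeg)
  if (is.null(labs) || anyDuplicated(labs))
    msg <- c(msg, "EEG channel labels must be present and unique")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: generator-side truth for every extracted quantity
#'
#' Everything the downstream extractors estimate is recorded here by the
#' synthetic generator so each stage can be validated against a known answer:
#' R-peak instants, blink instants, phasic driver impulses, the true tonic
#' skin-conductance curve, the true per-window LF/HF ratio, the per-slot
#' band-amplitude gains and the alpha peak frequency used for the EEG.
#'
#' @slot rPeakTimes,blinkTimes numeric, seconds.
#' @slot scrImpulses `data.frame(time, amplitude)`.
#' @slot artifactEpochs `data.frame(start, kind)` for injected EEG defects.
#' @slot tonicTime,tonic the true tonic curve (seconds / microsiemens).
#' @slot trueLfHf `data.frame(windowStart, lfhf)` per 30-s window.
#' @slot slotGain numeric amplitude multiplier per slot (stress channels).
#' @slot iaf numeric, the simulated alpha peak in Hz.
#' @slot seed integer seed the recording was generated from.
#' @export
setClass("GroundTruth",
  representation(
    rPeakTimes = "numeric", blinkTimes = "numeric",
    scrImpulses = "data.frame", artifactEpochs = "data.frame",
    tonicTime = "numeric", tonic = "numeric",
    trueLfHf = "data.frame", slotGain = "numeric",
    iaf = "numeric", seed = "integer"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  rp <- object@rPeakTimes
  if (length(rp) > 1 && any(diff(rp) < 0.2))
    msg <- c(msg, "rPeakTimes must be strictly increasing with gaps >= 0.2 s")
  if (nrow(object@scrImpulses) && any(object@scrImpulses$amplitude < 0))
    msg <- c(msg, "driver impulse amplitudes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SubjectiveRatings: 5-point operator and supervisor ratings
#'
#' One triple per rating instant: the operator's own stress rating, the
#' supervisor's stress rating and the supervisor's efficiency rating, all on
#' the 1 (none) to 5 (very high) scale.
#'
#' @slot times rating instants in seconds.
#' @slot atco,smeStress,smeEfficiency integer ratings in `[1, 5]`.
#' @export
setClass("SubjectiveRatings",
  representation(
    times = "numeric", atco = "integer",
    smeStress = "integer", smeEfficiency = "integer"
  )
)

setValidity("SubjectiveRatings", function(object) {
  v <- c(object@atco, object@smeStress, object@smeEfficiency)
  n <- length(object@times)
  msg <- character()
  if (any(v < 1L | v > 5L)) msg <- c(msg, "ratings must lie in [1, 5]")
  if (length(object@atco) != n || length(object@smeStress) != n ||
      length(object@smeEfficiency) != n)
    msg <- c(msg, "one rating triple per instant required")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# EEG feature containers
# ---------------------------------------------------------------------------

#' EpochSet: a windowed view of a multichannel signal
#'
#' Epochs are referenced by start sample against the stored signal rather
#' than materialised, so long sessions stay memory-light. The artifact mask
#' is filled in by [flagArtifacts()].
#'
#' @slot signal channels x samples matrix.
#' @slot fs sampling rate in Hz.
#' @slot win,shift window length and shift in seconds.
#' @slot startSamples 1-based start sample of each epoch.
#' @slot mask `data.frame` with logical columns `flagged`, `threshold`,
#'   `trend`, `sampleToSample` (empty until artifacts are flagged).
#' @export
setClass("EpochSet",
  representation(
    signal = "matrix", fs = "numeric",
    win = "numeric", shift = "numeric",
    startSamples = "integer", mask = "data.frame"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  st <- object@startSamples
  if (length(st) && any(diff(st) <= 0))
    msg <- c(msg, "epoch start samples must be strictly increasing")
  nSamp <- ncol(object@signal)
  L <- round(object@win * object@fs)
  if (length(st) && (max(st) + L - 1L) > nSamp)
    msg <- c(msg, "epochs must lie within the signal")
  if (nrow(object@mask) && nrow(object@mask) != length(st))
    msg <- c(msg, "mask must have one row per epoch")
  if (nrow(object@mask)) {
    bad <- object@mask$flagged &
      !(object@mask$threshold | object@mask$trend | object@mask$sampleToSample)
    if (any(bad)) msg <- c(msg, "flagged epochs must carry a reason code")
  }
  if (length(msg)) msg else TRUE
})

#' SpectralFeatures: per-epoch power spectra and band powers
#'
#' @slot psd epochs x channels x frequency-bin array of one-sided power
#'   spectral density (microvolt^2/Hz); only clean epochs are present.
#' @slot freqs frequency-bin centres in Hz (0.5-Hz spacing for 2-s epochs).
#' @slot epochStart start time in seconds of each retained epoch.
#' @slot iaf individual alpha frequency in Hz (`NA` until bands are set).
#' @slot bandEdges named list of `c(low, high)` per band.
#' @slot bandPower epochs x channels x band array (mean in-band PSD).
#' @export
setClass("SpectralFeatures",
  representation(
    psd = "array", freqs = "numeric", epochStart = "numeric",
    iaf = "numeric", bandEdges = "list", bandPower = "array"
  )
)

setValidity("SpectralFeatures", function(object) {
  msg <- character()
  if (length(object@psd) && min(object@psd) < 0)
    msg <- c(msg, "PSD must be non-negative")
  be <- object@bandEdges
  if (length(be) > 1) {
    lo <- vapply(be, `[`, numeric(1), 1L)
    hi <- vapply(be, `[`, numeric(1), 2L)
    if (any(hi <= lo)) msg <- c(msg, "band edges must be increasing")
    if (any(lo[-1] < hi[-length(hi)]))
      msg <- c(msg, "bands must be non-overlapping and ordered")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ECG / EDA containers
# ---------------------------------------------------------------------------

#' RRSeries: detected heartbeats and inter-beat intervals
#'
#' @slot beatTimes R-peak instants in seconds, strictly increasing.
#' @slot correctedFlags logical per interval: `TRUE` where the interval was
#'   replaced during artifact correction.
#' @export
setClass("RRSeries",
  representation(beatTimes = "numeric", correctedFlags = "logical")
)

setValidity("RRSeries", function(object) {
  msg <- character()
  bt <- object@beatTimes
  if (length(bt) > 1 && any(diff(bt) <= 0))
    msg <- c(msg, "beat times must be strictly increasing")
  if (length(object@correctedFlags) &&
      length(object@correctedFlags) != max(0L, length(bt) - 1L))
    msg <- c(msg, "one corrected flag per RR interval required")
  if (length(msg)) msg else TRUE
})

#' HRVWindows: windowed Lomb-Scargle heart-rate-variability features
#'
#' @slot windows `data.frame` with columns `windowStart`, `hrMean`, `lf`,
#'   `hf`, `lfhf`, `nBeats`, `missing`.
#' @slot window,step window length and step in seconds.
#' @slot resolution fundamental frequency resolution `1/window` in Hz.
#' @export
setClass("HRVWindows",
  representation(windows = "data.frame", window = "numeric",
                 step = "numeric", resolution = "numeric")
)

setValidity("HRVWindows", function(object) {
  w <- object@windows
  msg <- character()
  ok <- !w$missing
  if (any(w$lf[ok] < 0, na.rm = TRUE) || any(w$hf[ok] < 0, na.rm = TRUE))
    msg <- c(msg, "band powers must be non-negative")
  if (length(msg)) msg else TRUE
})

#' EDADecomposition: tonic/phasic split of skin conductance
#'
#' @slot time seconds (25 Hz grid by default).
#' @slot fs sampling rate of the decomposition in Hz.
#' @slot sc the smoothed conductance that was decomposed (microsiemens).
#' @slot tonic,phasic tonic and phasic components in microsiemens.
#' @slot driver non-negative deconvolved driver.
#' @slot tauRise,tauDecay biexponential impulse-response constants (s).
#' @export
setClass("EDADecomposition",
  representation(
    time = "numeric", fs = "numeric", sc = "numeric",
    tonic = "numeric", phasic = "numeric", driver = "numeric",
    tauRise = "numeric", tauDecay = "numeric"
  )
)

setValidity("EDADecomposition", function(object) {
  msg <- character()
  if (object@tauDecay <= object@tauRise || object@tauRise <= 0)
    msg <- c(msg, "need tauDecay > tauRise > 0")
  if (length(object@driver) && min(object@driver) < -1e-6)
    msg <- c(msg, "driver must be non-negative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Fusion and modelling containers
# ---------------------------------------------------------------------------

#' StressFeatureTable: merged multimodal features on a common time base
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one assay, `features` (features x windows), with per-window labels in
#' `colData`: `windowStart`, `slot`, `phase`, `workload`, `stress` and
#' `subject`.
#'
#' @export
setClass("StressFeatureTable", contains = "SummarizedExperiment")

setValidity("StressFeatureTable", function(object) {
  msg <- character()
  need <- c("windowStart", "slot", "phase", "workload", "stress", "subject")
  if (!all(need %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (length(msg)) msg else TRUE
})

#' SWLDAModel: a stepwise linear discriminant model
#'
#' Features are entered and removed by partial F-test p-values; the final
#' weights come from least-squares regression of the +/-1 class codes on the
#' selected columns.
#'
#' @slot selected ordered names of the selected features.
#' @slot weights numeric weights, one per selected feature.
#' @slot intercept numeric scalar.
#' @slot pEnter,pRemove entry/removal p-value thresholds.
#' @slot maxFeatures cap on the number of selected features.
#' @slot classes the two class labels, low then high (higher score = second).
#' @slot calibration `c(location, scale)` for the logistic mapping of scores
#'   to class probabilities, fitted on training scores.
#' @export
setClass("SWLDAModel",
  representation(
    selected = "character", weights = "numeric", intercept = "numeric",
    pEnter = "numeric", pRemove = "numeric", maxFeatures = "numeric",
    classes = "character", calibration = "numeric"
  )
)

setValidity("SWLDAModel", function(object) {
  msg <- character()
  if (object@pEnter >= object@pRemove)
    msg <- c(msg, "pEnter must be smaller than pRemove")
  if (length(object@selected) > object@maxFeatures)
    msg <- c(msg, "more features selected than maxFeatures allows")
  if (length(object@weights) != length(object@selected))
    msg <- c(msg, "one weight per selected feature required")
  if (length(msg)) msg else TRUE
})

#' StressIndexSeries: the fold-averaged discriminant output
#'
#' @slot time window start times (seconds) of scored steps.
#' @slot y fold-averaged discriminant value per step.
#' @slot nFolds number of cross-validation folds contributing to each step.
#' @export
setClass("StressIndexSeries",
  representation(time = "numeric", y = "numeric", nFolds = "integer")
)

setValidity("StressIndexSeries", function(object) {
  msg <- character()
  if (length(object@y) != length(object@time) ||
      length(object@nFolds) != length(object@time))
    msg <- c(msg, "time, y and nFolds must be parallel")
  if (length(object@nFolds) && any(object@nFolds < 1L))
    msg <- c(msg, "index values require at least one contributing fold")
  if (length(msg)) msg else TRUE
})

#' FriedmanResult: Friedman rank test with post-hoc comparisons
#'
#' @slot chiSquare test statistic on the mid-rank formulation.
#' @slot p p-value from the chi-square reference distribution.
#' @slot n,k subjects and conditions.
#' @slot posthoc `data.frame` of pairwise signed-rank comparisons with
#'   Bonferroni-corrected p-values (empty when the omnibus test is null).
#' @export
setClass("FriedmanResult",
  representation(chiSquare = "numeric", p = "numeric",
                 n = "integer", k = "integer", posthoc = "data.frame")
)

#' RmcorrResult: repeated-measures (within-subject) correlation
#'
#' @slot r common within-subject correlation in `[-1, 1]`.
#' @slot p p-value from the F reference distribution.
#' @slot dof error degrees of freedom (`N - subjects - 1`).
#' @slot slope the shared within-subject slope.
#' @export
setClass("RmcorrResult",
  representation(r = "numeric", p = "numeric", dof = "integer",
                 slope = "numeric")
)
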