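# Accessor generics and show methods. Slot access from user code goes through
# these; the slots themselves are implementation detail.

#' @rdname ScenarioTimeline-class
#' @param object,x a package object.
#' @export
setGeneric("sessionDuration", function(object) standardGeneric("sessionDuration"))

#' @rdname ScenarioTimeline-class
#' @export
setGeneric("slotTable", function(object) standardGeneric("slotTable"))

#' @rdname ScenarioTimeline-class
#' @export
setGeneric("phaseTable", function(object) standardGeneric("phaseTable"))

#' @rdname ScenarioTimeline-class
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' @rdname ScenarioTimeline-class
#' @export
setGeneric("ratingTimes", function(object) standardGeneric("ratingTimes"))

setMethod("sessionDuration", "ScenarioTimeline", function(object) object@totalDuration)
setMethod("slotTable", "ScenarioTimeline", function(object) object@slots)
setMethod("phaseTable", "ScenarioTimeline", function(object) object@phases)
setMethod("eventTable", "ScenarioTimeline", function(object) object@events)
setMethod("ratingTimes", "ScenarioTimeline", function(object) object@ratingTimes)

setMethod("show", "ScenarioTimeline", function(object) {
  cat(sprintf("ScenarioTimeline: %g s, %d slots / %d phases, %d stress events\n",
              object@totalDuration, nrow(object@slots), nrow(object@phases),
              nrow(object@events)))
  cat("  slot stress:", paste(object@slots$stress, collapse = " -> "), "\n")
})

#' @rdname MultimodalRecording-class
#' @param object a `MultimodalRecording`.
#' @export
setGeneric("eegSignal", function(object) standardGeneric("eegSignal"))

#' @rdname MultimodalRecording-class
#' @export
setGeneric("ecgSignal", function(object) standardGeneric("ecgSignal"))

#' @rdname MultimodalRecording-class
#' @export
setGeneric("gsrSignal", function(object) standardGeneric("gsrSignal"))

#' @rdname MultimodalRecording-class
#' @export
setGeneric("ocBaseline", function(object) standardGeneric("ocBaseline"))

#' @rdname MultimodalRecording-class
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname MultimodalRecording-class
#' @export
setGeneric("samplingRates", function(object) standardGeneric("samplingRates"))

setMethod("eegSignal", "MultimodalRecording", function(object) object@eeg)
setMethod("ecgSignal", "MultimodalRecording", function(object) object@ecg)
setMethod("gsrSignal", "MultimodalRecording", function(object) object@gsr)
setMethod("ocBaseline", "MultimodalRecording", function(object) object@ocBaseline)
setMethod("channelLabels", "MultimodalRecording", function(object) rownames(object@eeg))
setMethod("samplingRates", "MultimodalRecording", function(object)
  c(eeg = object@eegRate, ecg = object@ecgRate, gsr = object@gsrRate))

setMethod("show", "MultimodalRecording", function(object) {
  cat(sprintf("MultimodalRecording: %d EEG channels @ %g Hz (%.1f s), ECG @ %g Hz, GSR @ %g Hz\n",
              nrow(object@eeg), object@eegRate, ncol(object@eeg) / object@eegRate,
              object@ecgRate, object@gsrRate))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d R peaks, %d blinks, %d SCR impulses, %d injected EEG defects (seed %d)\n",
              length(object@rPeakTimes), length(object@blinkTimes),
              nrow(object@scrImpulses), nrow(object@artifactEpochs), object@seed))
})

setMethod("show", "SubjectiveRatings", function(object) {
  cat(sprintf("SubjectiveRatings: %d instants; ATCO stress %s; SME stress %s\n",
              length(object@times),
              paste(range(object@atco), collapse = "-"),
              paste(range(object@smeStress), collapse = "-")))
})

#' @rdname EpochSet-class
#' @param object an `EpochSet`.
#' @export
setGeneric("epochCount", function(object) standardGeneric("epochCount"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochStartTimes", function(object) standardGeneric("epochStartTimes"))

#' @rdname EpochSet-class
#' @export
setGeneric("artifactMask", function(object) standardGeneric("artifactMask"))

#' @rdname EpochSet-class
#' @export
setGeneric("epochMatrix", function(object, i) standardGeneric("epochMatrix"))

setMethod("epochCount", "EpochSet", function(object) length(object@startSamples))
setMethod("epochStartTimes", "EpochSet", function(object)
  (object@startSamples - 1L) / object@fs)
setMethod("artifactMask", "EpochSet", function(object) object@mask)

#' @rdname EpochSet-class
#' @param i epoch index.
setMethod("epochMatrix", "EpochSet", function(object, i) {
  L <- round(object@win * object@fs)
  s <- object@startSamples[i]
  object@signal[, s:(s + L - 1L), drop = FALSE]
})

setMethod("show", "EpochSet", function(object) {
  nFlag <- if (nrow(object@mask)) sum(object@mask$flagged) else NA_integer_
  cat(sprintf("EpochSet: %d epochs of %g s (shift %g s), %d channels, flagged: %s\n",
              epochCount(object), object@win, object@shift, nrow(object@signal),
              ifelse(is.na(nFlag), "<not screened>", as.character(nFlag))))
})

#' @rdname SpectralFeatures-class
#' @param object a `SpectralFeatures`.
#' @export
setGeneric("psdArray", function(object) standardGeneric("psdArray"))

#' @rdname SpectralFeatures-class
#' @export
setGeneric("psdFrequencies", function(object) standardGeneric("psdFrequencies"))

#' @rdname SpectralFeatures-class
#' @export
setGeneric("bandEdges", function(object) standardGeneric("bandEdges"))

#' @rdname SpectralFeatures-class
#' @export
setGeneric("bandPowerArray", function(object) standardGeneric("bandPowerArray"))

setMethod("psdArray", "SpectralFeatures", function(object) object@psd)
setMethod("psdFrequencies", "SpectralFeatures", function(object) object@freqs)
setMethod("bandEdges", "SpectralFeatures", function(object) object@bandEdges)
setMethod("bandPowerArray", "SpectralFeatures", function(object) object@bandPower)

setMethod("show", "SpectralFeatures", function(object) {
  d <- dim(object@psd)
  cat(sprintf("SpectralFeatures: %d epochs x %d channels x %d bins (%.2g-%.2g Hz)\n",
              d[1], d[2], d[3], min(object@freqs), max(object@freqs)))
  if (length(object@bandEdges))
    cat("  bands:", paste(sprintf("%s[%g,%g)", names(object@bandEdges),
        vapply(object@bandEdges, `[`, numeric(1), 1),
        vapply(object@bandEdges, `[`, numeric(1), 2)), collapse = " "), "\n")
})

#' @rdname RRSeries-class
#' @param object an `RRSeries`.
#' @export
setGeneric("beatTimes", function(object) standardGeneric("beatTimes"))

#' @rdname RRSeries-class
#' @export
setGeneric("rrIntervals", function(object) standardGeneric("rrIntervals"))

#' @rdname RRSeries-class
#' @export
setGeneric("correctedFlags", function(object) standardGeneric("correctedFlags"))

setMethod("beatTimes", "RRSeries", function(object) object@beatTimes)
setMethod("rrIntervals", "RRSeries", function(object) diff(object@beatTimes))
setMethod("correctedFlags", "RRSeries", function(object) object@correctedFlags)

setMethod("show", "RRSeries", function(object) {
  n <- length(object@beatTimes)
  cat(sprintf("RRSeries: %d beats", n))
  if (n > 1)
    cat(sprintf(", mean HR %.1f bpm, %d corrected intervals",
                60 / mean(diff(object@beatTimes)), sum(object@correctedFlags)))
  cat("\n")
})

#' @rdname HRVWindows-class
#' @param object an `HRVWindows`.
#' @export
setGeneric("hrvTable", function(object) standardGeneric("hrvTable"))

#' @rdname HRVWindows-class
#' @export
setGeneric("frequencyResolution", function(object) standardGeneric("frequencyResolution"))

setMethod("hrvTable", "HRVWindows", function(object) object@windows)
setMethod("frequencyResolution", "HRVWindows", function(object) object@resolution)

setMethod("show", "HRVWindows", function(object) {
  w <- object@windows
  cat(sprintf("HRVWindows: %d windows of %g s (res. %.3f Hz), %d missing\n",
              nrow(w), object@window, object@resolution, sum(w$missing)))
})

#' @rdname EDADecomposition-class
#' @param object an `EDADecomposition`.
#' @export
setGeneric("tonicComponent", function(object) standardGeneric("tonicComponent"))

#' @rdname EDADecomposition-class
#' @export
setGeneric("phasicComponent", function(object) standardGeneric("phasicComponent"))

#' @rdname EDADecomposition-class
#' @export
setGeneric("driverSignal", function(object) standardGeneric("driverSignal"))

setMethod("tonicComponent", "EDADecomposition", function(object) object@tonic)
setMethod("phasicComponent", "EDADecomposition", function(object) object@phasic)
setMethod("driverSignal", "EDADecomposition", function(object) object@driver)

setMethod("show", "EDADecomposition", function(object) {
  cat(sprintf("EDADecomposition: %.1f s @ %g Hz, tonic %.2f-%.2f uS, IRF (%g, %g) s\n",
              length(object@tonic) / object@fs, object@fs,
              min(object@tonic), max(object@tonic),
              object@tauRise, object@tauDecay))
})

#' @rdname SWLDAModel-class
#' @param object an `SWLDAModel`.
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname SWLDAModel-class
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))

setMethod("selectedFeatures", "SWLDAModel", function(object) object@selected)
setMethod("modelWeights", "SWLDAModel", function(object)
  setNames(object@weights, object@selected))

setMethod("show", "SWLDAModel", function(object) {
  cat(sprintf("SWLDAModel: %d features (pEnter %.2g, pRemove %.2g), classes %s < %s\n",
              length(object@selected), object@pEnter, object@pRemove,
              object@classes[1], object@classes[2]))
  if (length(object@selected))
    cat("  ", paste(head(object@selected, 8), collapse = ", "),
        if (length(object@selected) > 8) "..." else "", "\n")
})

#' @rdname StressIndexSeries-class
#' @param object a `StressIndexSeries`.
#' @export
setGeneric("indexValues", function(object) standardGeneric("indexValues"))

#' @rdname StressIndexSeries-class
#' @export
setGeneric("indexTimes", function(object) standardGeneric("indexTimes"))

#' @rdname StressIndexSeries-class
#' @export
setGeneric("foldCounts", function(object) standardGeneric("foldCounts"))

setMethod("indexValues", "StressIndexSeries", function(object) object@y)
setMethod("indexTimes", "StressIndexSeries", function(object) object@time)
setMethod("foldCounts", "StressIndexSeries", function(object) object@nFolds)

setMethod("show", "StressIndexSeries", function(object) {
  cat(sprintf("StressIndexSeries: %d steps, y in [%.3g, %.3g]\n",
              length(object@y), min(object@y), max(object@y)))
})

setMethod("show", "FriedmanResult", function(object) {
  cat(sprintf("Friedman rank test: chi^2 = %.3f (k = %d, n = %d), p = %.4g\n",
              object@chiSquare, object@k, object@n, object@p))
  if (nrow(object@posthoc)) {
    cat("  post-hoc (Bonferroni-corrected signed-rank):\n")
    print(object@posthoc, row.names = FALSE)
  }
})

setMethod("show", "RmcorrResult", function(object) {
  cat(sprintf("Repeated-measures correlation: r = %.3f, dof = %d, p = %.4g\n",
              object@r, object@dof, object@p))
})
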