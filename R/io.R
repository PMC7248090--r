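# Plain-text interchange: long-format CSV for raw signals, YAML for the
# timeline, CSV for ratings and feature tables, JSON for the ground truth.

#' Write a recording to long-format CSV files
#'
#' Writes `eeg.csv` (`time_s, channel, value`), `ecg.csv` and `gsr.csv`
#' (`time_s, value`) into `dir`. Intended for interchange of short sessions;
#' the files are plain text and grow with the sampling rate.
#'
#' @param recording a [MultimodalRecording-class].
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
writeRecordingCsv <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eeg <- eegSignal(recording)
  tE <- (seq_len(ncol(eeg)) - 1) / samplingRates(recording)[["eeg"]]
  long <- data.frame(
    time_s = rep(tE, each = nrow(eeg)),
    channel = rep(rownames(eeg), times = ncol(eeg)),
    value = as.vector(eeg))
  fE <- file.path(dir, "eeg.csv")
  write.csv(long, fE, row.names = FALSE)
  ecg <- ecgSignal(recording)
  fC <- file.path(dir, "ecg.csv")
  write.csv(data.frame(
    time_s = (seq_along(ecg) - 1) / samplingRates(recording)[["ecg"]],
    value = ecg), fC, row.names = FALSE)
  gsr <- gsrSignal(recording)
  fG <- file.path(dir, "gsr.csv")
  write.csv(data.frame(
    time_s = (seq_along(gsr) - 1) / samplingRates(recording)[["gsr"]],
    value = gsr), fG, row.names = FALSE)
  invisible(c(fE, fC, fG))
}

#' Read an EEG long-format CSV back into a channels x samples matrix
#' @param path CSV written by [writeRecordingCsv()].
#' @return matrix with channel rownames, attribute `fs`.
#' @export
readEegCsv <- function(path) {
  d <- read.csv(path)
  chans <- unique(d$channel)
  tms <- sort(unique(d$time_s))
  m <- matrix(NA_real_, length(chans), length(tms),
              dimnames = list(chans, NULL))
  m[cbind(match(d$channel, chans), match(d$time_s, tms))] <- d$value
  attr(m, "fs") <- 1 / median(diff(tms))
  m
}

#' Write / read the timeline as YAML
#' @param timeline a [ScenarioTimeline-class].
#' @param path YAML file.
#' @export
writeTimelineYaml <- function(timeline, path) {
  yaml::write_yaml(list(
    total_duration = sessionDuration(timeline),
    slots = slotTable(timeline),
    phases = phaseTable(timeline),
    events = eventTable(timeline),
    rating_times = ratingTimes(timeline)), path)
  invisible(path)
}

#' @rdname writeTimelineYaml
#' @export
readTimelineYaml <- function(path) {
  d <- yaml::read_yaml(path)
  asDf <- function(x) as.data.frame(lapply(x, unlist),
                                    stringsAsFactors = FALSE)
  new("ScenarioTimeline",
      totalDuration = d$total_duration,
      slots = asDf(d$slots), phases = asDf(d$phases),
      events = asDf(d$events), ratingTimes = unlist(d$rating_times))
}

#' Write ratings as CSV
#' @param ratings a [SubjectiveRatings-class].
#' @param path CSV file.
#' @export
writeRatingsCsv <- function(ratings, path) {
  write.csv(data.frame(
    time_s = ratings@times, atco_stress = ratings@atco,
    sme_stress = ratings@smeStress, sme_efficiency = ratings@smeEfficiency),
    path, row.names = FALSE)
  invisible(path)
}

#' Write the generator ground truth as a JSON sidecar
#' @param truth a [GroundTruth-class].
#' @param path JSON file.
#' @export
writeGroundTruthJson <- function(truth, path) {
  jsonlite::write_json(list(
    r_peak_times = truth@rPeakTimes,
    blink_times = truth@blinkTimes,
    scr_impulses = truth@scrImpulses,
    artifact_epochs = truth@artifactEpochs,
    tonic = data.frame(time = truth@tonicTime, value = truth@tonic),
    true_lfhf = truth@trueLfHf,
    slot_gain = truth@slotGain, iaf = truth@iaf, seed = truth@seed),
    path, digits = NA)
  invisible(path)
}

#' Write / read a feature table as CSV
#'
#' One row per window: the label columns (`window_start_s, slot, phase,
#' workload, stress, subject`) followed by one column per feature.
#'
#' @param table a [StressFeatureTable-class].
#' @param path CSV file.
#' @export
writeFeatureTable <- function(table, path) {
  lab <- windowLabels(table)
  d <- cbind(data.frame(window_start_s = lab$windowStart, slot = lab$slot,
                        phase = lab$phase, workload = lab$workload,
                        stress = lab$stress, subject = lab$subject),
             as.data.frame(featureMatrix(table)))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  labCols <- c("window_start_s", "slot", "phase", "workload", "stress",
               "subject")
  X <- as.matrix(d[, setdiff(colnames(d), labCols), drop = FALSE])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    colData = S4Vectors::DataFrame(
      windowStart = d$window_start_s, slot = d$slot, phase = d$phase,
      workload = d$workload, stress = d$stress, subject = d$subject))
  new("StressFeatureTable", se)
}

#' Write a stress-index series as CSV
#' @param index a [StressIndexSeries-class].
#' @param path CSV file.
#' @export
writeIndexCsv <- function(index, path) {
  write.csv(data.frame(time_s = indexTimes(index), y = indexValues(index),
                       n_folds = foldCounts(index)),
            path, row.names = FALSE)
  invisible(path)
}
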