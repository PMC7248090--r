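# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code; the heavy ones (full-session extraction, the
# multi-subject cohort) are reused across test files.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]]))
    assign(name, builder(), envir = .fixtureCache)
  .fixtureCache[[name]]
}

# Full extraction chain for one synthetic subject.
extractSubject <- function(timeline, seed, params = recordingParams(),
                           extended = FALSE) {
  sim <- generateRecording(timeline, params, seed = seed)
  rec <- sim$recording
  eeg <- bandpassEeg(eegSignal(rec), 256)
  rownames(eeg) <- rownames(eegSignal(rec))
  eeg <- correctBlinks(eeg, 256)
  ep <- flagArtifacts(epochSignal(eeg, 256))
  sp <- computePsd(ep)
  iaf <- estimateIaf(ocBaseline(rec), 256)
  sp <- bandPowers(sp, iaf)
  rr <- correctRr(detectRPeaks(bandpassEcg(ecgSignal(rec), 256), 256))
  hrv <- lombScargleHrv(rr, duration = sessionDuration(timeline))
  dec <- cdaDecompose(downsampleGsr(gsrSignal(rec)))
  ew <- windowEda(dec)
  ft <- suppressMessages(
    mergeFeatures(sp, hrv, ew, timeline, subject = paste0("S", seed)))
  out <- list(truth = sim$truth, epochs = ep, spectral = sp, iaf = iaf,
              rr = rr, hrv = hrv, decomposition = dec, eda = ew, table = ft,
              ratings = generateRatings(timeline, seed = seed))
  if (extended)
    out$tableExt <- suppressMessages(
      mergeFeatures(sp, hrv, ew, timeline, subject = paste0("S", seed),
                    includeHr = TRUE, includeScr = TRUE))
  out
}

# One subject, 720-s session, full raw-signal pipeline.
singleSubject720 <- function() fixture("single720", function() {
  tl <- generateTimeline(720)
  c(list(timeline = tl), extractSubject(tl, seed = 101))
})

# Eight-subject cohort on 720-s sessions (scaled-down study conditions),
# including per-subject cross-validated stress indexes.
cohort720 <- function() fixture("cohort720", function() {
  tl <- generateTimeline(720)
  subs <- lapply(1:8, function(s) {
    sub <- extractSubject(tl, seed = 200 + s, extended = TRUE)
    sub$cv <- runCrossValidation(sub$table, tl, seed = 300 + s)
    sub$eval <- evaluateStress(sub$cv, sub$table)
    sub$null <- suppressWarnings(
      permutationNull(sub$table, tl, nPerm = 99, seed = 600 + s))
    sub
  })
  list(timeline = tl, subjects = subs)
})

# One subject at the canonical 3600-s session for the bookkeeping checks.
fullSession3600 <- function() fixture("full3600", function() {
  tl <- generateTimeline(3600)
  c(list(timeline = tl), extractSubject(tl, seed = 401))
})

# Per-slot mean of a per-window quantity keyed by the table labels.
slotMeans <- function(values, labels) {
  vapply(1:4, function(s) mean(values[labels$slot == s]), numeric(1))
}
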