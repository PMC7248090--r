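test_that("EEG band-pass keeps in-band tones and rejects drift and DC", {
  fs <- 256
  t <- seq(0, 10, by = 1 / fs)
  inBand <- sin(2 * pi * 20 * t)
  out <- bandpassEeg(inBand, fs)
  mid <- seq(2 * fs, 8 * fs)
  expect_lt(abs(max(abs(out[mid])) - 1), 0.05)
  drift <- 100 * sin(2 * pi * 0.1 * t)
  expect_lt(max(abs(bandpassEeg(drift, fs)[mid])), 0.05 * 100)
  dc <- rep(50, length(t))
  expect_lt(mean(abs(bandpassEeg(dc, fs)[mid])), 1)
  expect_error(bandpassEeg(inBand, fs, high = 200), "Nyquist")
})

test_that("blink correction removes injected blinks and nothing else", {
  fs <- 256
  n <- 30 * fs
  set.seed(5)
  chans <- c("Fpz", "Fz", "Pz")
  clean <- rbind(Fpz = 4 * sin(2 * pi * 10 * seq_len(n) / fs),
                 Fz = rnorm(n, 0, 3),
                 Pz = rnorm(n, 0, 3))
  # no blinks: exact no-op outside numerical noise
  noBlink <- correctBlinks(clean, fs)
  expect_equal(unname(noBlink[, ]), unname(clean), tolerance = 1e-12)

  tpl <- stressfusion:::blinkTemplate(fs, 150)
  att <- c(Fpz = 1, Fz = 0.45, Pz = 0.1)
  dirty <- clean
  onsets <- c(5, 12, 21) * fs
  for (o in onsets) {
    idx <- o + seq_along(tpl)
    dirty[, idx] <- dirty[, idx] + att %o% tpl
  }
  corr <- correctBlinks(dirty, fs)
  iv <- attr(corr, "blinkIntervals")
  expect_equal(nrow(iv), 3)
  blinkSamples <- unlist(lapply(onsets, function(o) o + seq_along(tpl)))
  for (ch in chans) {
    rmse <- sqrt(mean((corr[ch, blinkSamples] - clean[ch, blinkSamples])^2))
    expect_lt(rmse, 0.2 * 150 * att[ch])
  }
  outside <- setdiff(seq_len(n), unlist(lapply(seq_len(nrow(iv)), function(j)
    seq(round(iv$start[j] * fs) + 1, round(iv$end[j] * fs) + 1))))
  expect_equal(corr["Fz", outside], dirty["Fz", outside])

  # blink confined to Fpz: zero regression coefficient elsewhere
  solo <- matrix(0, 3, n, dimnames = list(chans, NULL))
  solo["Fpz", onsets[1] + seq_along(tpl)] <- tpl
  corrSolo <- correctBlinks(solo, fs)
  expect_equal(max(abs(corrSolo["Fz", ])), 0)
  expect_equal(max(abs(corrSolo["Pz", ])), 0)
  expect_lt(max(abs(corrSolo["Fpz", ])), 15)   # blink mostly removed

  expect_error(correctBlinks(clean[2:3, ], fs), "not found")
  expect_warning(correctBlinks(clean[2:3, ], fs, allowMissing = TRUE),
                 "skipped")
})

test_that("epoching follows the floor((T - win)/shift) + 1 count", {
  fs <- 256
  x <- matrix(rnorm(60 * fs), 1)
  expect_equal(epochCount(epochSignal(x, fs)), 465)
  expect_equal(epochCount(epochSignal(matrix(0, 1, 2 * fs), fs)), 1)
  expect_error(epochSignal(matrix(0, 1, fs), fs), "shorter")
  st <- epochStartTimes(epochSignal(x, fs))
  expect_equal(diff(st), rep(0.125, 464))
})

test_that("each artifact criterion fires on its own defect class only", {
  fs <- 256
  L <- 2 * fs
  t <- (seq_len(L) - 1) / fs
  mk <- function(v) epochSignal(matrix(v, 1), fs)
  clean <- flagArtifacts(mk(rep(0, L)))
  expect_false(any(artifactMask(clean)$flagged))

  spike <- rep(0, L); spike[300] <- 120          # amplitude + jump together
  m <- artifactMask(flagArtifacts(mk(spike)))
  expect_true(m$threshold)

  highAmp <- 120 * cos(2 * pi * 5 * t)           # smooth, large amplitude
  m <- artifactMask(flagArtifacts(mk(highAmp)))
  expect_true(m$threshold)
  expect_false(m$trend); expect_false(m$sampleToSample)

  ramp <- 15 * t                                  # 15 uV/s, peak 30 uV
  m <- artifactMask(flagArtifacts(mk(ramp)))
  expect_true(m$trend)
  expect_false(m$threshold); expect_false(m$sampleToSample)

  jump <- rep(0, L); jump[256] <- 30              # one-sample 30 uV excursion
  m <- artifactMask(flagArtifacts(mk(jump)))
  expect_true(m$sampleToSample)
  expect_false(m$threshold)
  expect_false(m$trend)

  slow <- 5 * t                                   # 5 uV/s: below all criteria
  expect_false(any(artifactMask(flagArtifacts(mk(slow)))$flagged))
})

test_that("flagged fraction rises with the injected defect rate", {
  tl <- generateTimeline(240, eventDuration = 10)
  frac <- vapply(c(0, 5, 20), function(rate) {
    rec <- generateRecording(tl, recordingParams(artifactRate = rate,
                                                 blinkRate = 0),
                             seed = 31)$recording
    ep <- flagArtifacts(epochSignal(eegSignal(rec), 256))
    mean(artifactMask(ep)$flagged)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], frac[1])
})

test_that("periodogram has 0.5 Hz bins, locates tones, and obeys Parseval", {
  fs <- 256
  t <- (seq_len(2 * fs) - 1) / fs
  sp <- computePsd(epochSignal(matrix(sin(2 * pi * 10 * t), 1), fs),
                   maxFreq = fs / 2)
  f <- psdFrequencies(sp)
  expect_equal(unique(round(diff(f), 9)), 0.5)
  expect_equal(f[which.max(psdArray(sp)[1, 1, ])], 10)

  set.seed(8)
  x <- rnorm(2 * fs)
  spw <- computePsd(epochSignal(matrix(x, 1), fs), maxFreq = fs / 2)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(2 * fs) - 1) / (2 * fs - 1))
  oracle <- sum((w * x)^2) / sum(w^2)            # tapered power, Parseval
  expect_equal(sum(psdArray(spw)[1, 1, ]) * 0.5, oracle, tolerance = 0.01)

  ep <- flagArtifacts(epochSignal(matrix(rep(200, 2 * fs), 1), fs))
  expect_error(computePsd(ep), "no clean epochs")
})

test_that("IAF is recovered within half a bin and falls back on white noise", {
  fs <- 256
  n <- 40 * fs
  mkBase <- function(f0) {
    set.seed(13)
    po <- c("Pz", "POz", "O1")
    m <- do.call(rbind, lapply(po, function(ch)
      rnorm(n, 0, 3) + 6 * sin(2 * pi * f0 * (seq_len(n) - 1) / fs)))
    rownames(m) <- po
    m
  }
  i1 <- estimateIaf(mkBase(10.5), fs)
  expect_lt(abs(i1 - 10.5), 0.5 + 1e-9)
  expect_true(attr(i1, "peakFound"))
  i2 <- estimateIaf(mkBase(9), fs)
  expect_lt(abs(i2 - 9), 0.5 + 1e-9)
  set.seed(14)
  flat <- matrix(rnorm(2 * n, 0, 3), 2, dimnames = list(c("Pz", "O1"), NULL))
  expect_warning(i3 <- estimateIaf(flat, fs), "falling back")
  expect_equal(as.numeric(i3), 10)
  expect_false(attr(i3, "peakFound"))
  expect_error(estimateIaf(flat[, 1:(20 * fs)], fs), "30 s")
})

test_that("IAF-anchored bands are placed and averaged correctly", {
  expect_equal(iafBandEdges(10)$alpha, c(8, 12))
  expect_equal(iafBandEdges(10)$theta, c(4, 8))
  expect_equal(iafBandEdges(10)$gamma, c(26, 40))
  fs <- 256
  t <- (seq_len(2 * fs) - 1) / fs
  sp <- computePsd(epochSignal(matrix(sin(2 * pi * 10 * t), 1), fs))
  sp <- bandPowers(sp, iaf = 10)
  bp <- bandPowerArray(sp)[1, 1, ]
  expect_gt(bp["alpha"] / bp["theta"], 10)
  expect_gt(bp["alpha"] / bp["beta"], 10)
  expect_gt(bp["alpha"] / bp["gamma"], 10)
  expect_error(bandPowers(sp, iaf = 5), "\\[7, 13\\]")
  # 4 bands x 16 channels = 64 per-epoch features before channel selection
  sp16 <- bandPowers(computePsd(epochSignal(
    matrix(rnorm(16 * 2 * fs), 16,
           dimnames = list(eegMontage(), NULL)), fs)), iaf = 10)
  expect_equal(prod(dim(bandPowerArray(sp16))[2:3]), 64)
})

test_that("stress slots raise band power on the configured channels", {
  co <- cohort720()
  lab <- windowLabels(co$subjects[[1]]$table)
  m1 <- vapply(co$subjects, function(s)
    mean(featureMatrix(s$table)[windowLabels(s$table)$slot == 1,
                                featureNames(c("Fz", "POz"))]), numeric(1))
  m3 <- vapply(co$subjects, function(s)
    mean(featureMatrix(s$table)[windowLabels(s$table)$slot == 3,
                                featureNames(c("Fz", "POz"))]), numeric(1))
  expect_true(all(m3 > m1))
  expect_lt(wilcoxonSignedRank(m3, m1)$p.value, 0.05)
})
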