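# helpers to synthesise ECG with known beat times
mkEcg <- function(beatTimes, fs = 256, dur = NULL, noiseSd = 0) {
  if (is.null(dur)) dur <- max(beatTimes) + 1
  tpl <- stressfusion:::qrsTemplate(fs)
  n <- round(dur * fs)
  x <- rnorm(n, 0, noiseSd)
  off <- round(tpl$t[1] * fs)
  for (bt in beatTimes) {
    idx <- round(bt * fs) + 1 + off + seq_along(tpl$y) - 1
    keep <- idx >= 1 & idx <= n
    x[idx[keep]] <- x[idx[keep]] + tpl$y[keep]
  }
  x
}

matchBeats <- function(est, truth, tol = 0.05) {
  tp <- sum(vapply(truth, function(b) any(abs(est - b) <= tol), logical(1)))
  fp <- sum(vapply(est, function(b) all(abs(truth - b) > tol), logical(1)))
  c(sensitivity = tp / length(truth),
    ppv = (length(est) - fp) / max(1, length(est)))
}

test_that("ECG band-pass suppresses mains and baseline, keeps QRS band", {
  fs <- 256
  t <- seq(0, 10, by = 1 / fs)
  mid <- seq(2 * fs, 8 * fs)
  mains <- sin(2 * pi * 50 * t)
  expect_lt(max(abs(bandpassEcg(mains, fs)[mid])), 0.05)
  qrs <- sin(2 * pi * 10 * t)
  expect_lt(abs(max(abs(bandpassEcg(qrs, fs)[mid])) - 1), 0.05)
  expect_lt(mean(abs(bandpassEcg(rep(1, length(t)), fs)[mid])), 0.01)
  expect_error(bandpassEcg(qrs, 30), "exceed")
  expect_error(bandpassEcg(qrs, fs, low = 25, high = 20), "invalid")
})

test_that("Pan-Tompkins recovers clean beats to within 10 ms", {
  fs <- 256
  truth <- seq(0.5, 59.5, by = 1)               # 60 bpm
  set.seed(21)
  rr <- detectRPeaks(bandpassEcg(mkEcg(truth, fs, 60, noiseSd = 0.01), fs), fs)
  bt <- beatTimes(rr)
  expect_lte(abs(length(bt) - 60), 1)
  err <- vapply(bt, function(b) min(abs(truth - b)), numeric(1))
  expect_lt(max(err), 0.010 + 1e-9)
})

test_that("detection sensitivity and PPV hold across seeds and at 10 dB SNR", {
  fs <- 256
  for (s in 1:3) {
    set.seed(s)
    truth <- cumsum(c(0.5, 60 / rnorm(70, 70, 2)))
    truth <- truth[truth < 60]
    clean <- mkEcg(truth, fs, 60)
    det <- beatTimes(detectRPeaks(bandpassEcg(clean, fs), fs))
    m <- matchBeats(det, truth)
    expect_gte(m[["sensitivity"]], 0.99)
    expect_gte(m[["ppv"]], 0.99)
    snr <- 10
    noiseSd <- sqrt(mean(clean^2) / 10^(snr / 10))
    noisy <- clean + rnorm(length(clean), 0, noiseSd)
    mN <- matchBeats(beatTimes(detectRPeaks(bandpassEcg(noisy, fs), fs)), truth)
    expect_gte(mN[["sensitivity"]], 0.95)
  }
})

test_that("alternating rhythms and degenerate signals are handled", {
  fs <- 256
  truth <- cumsum(c(0.5, rep(c(0.8, 1.0), 30)))
  rr <- detectRPeaks(bandpassEcg(mkEcg(truth, fs), fs), fs)
  est <- rrIntervals(rr)
  expect_true(all(abs(est[seq(1, 50, 2)] - est[1]) < 0.04))
  expect_true(all(abs(sort(unique(round(est, 1))) - c(0.8, 1.0)) < 0.02))
  expect_warning(rrFlat <- detectRPeaks(rep(0, 20 * fs), fs), "no R peaks")
  expect_length(beatTimes(rrFlat), 0)
  expect_error(detectRPeaks(rep(0, fs), fs), "10 s")
})

test_that("RR correction replaces local-median outliers only", {
  bt <- cumsum(c(0, rep(1, 30)))
  rr0 <- new("RRSeries", beatTimes = bt, correctedFlags = logical(30))
  out <- correctRr(rr0)
  expect_identical(beatTimes(out), bt)
  expect_false(any(correctedFlags(out)))

  btBad <- cumsum(c(0, rep(1, 14), 0.4, rep(1, 14)))
  rrB <- new("RRSeries", beatTimes = btBad, correctedFlags = logical(29))
  fixed <- correctRr(rrB)
  expect_equal(sum(correctedFlags(fixed)), 1)
  expect_equal(rrIntervals(fixed)[15], 1.0, tolerance = 0.05)

  allBad <- new("RRSeries", beatTimes = cumsum(c(0, rep(c(0.4, 1.6), 10))),
                correctedFlags = logical(20))
  expect_error(correctRr(allBad), "unreliable")
})

test_that("Lomb-Scargle separates LF and HF modulation", {
  mkRr <- function(f, a = 0.05, a2 = 0, f2 = 0.3) {
    bt <- 0
    repeat {
      nxt <- bt[length(bt)] + 0.85 * (1 + a * sin(2 * pi * f * bt[length(bt)]) +
                                        a2 * sin(2 * pi * f2 * bt[length(bt)]))
      if (nxt > 120) break
      bt <- c(bt, nxt)
    }
    new("RRSeries", beatTimes = bt, correctedFlags = logical(length(bt) - 1))
  }
  hLf <- hrvTable(lombScargleHrv(mkRr(0.1), duration = 120))
  expect_true(all(hLf$lfhf > 10))
  hHf <- hrvTable(lombScargleHrv(mkRr(0.3), duration = 120))
  expect_true(all(hHf$lfhf < 0.1))
  # equal-amplitude LF + HF: ratio near 1, checked against a dense-grid
  # FFT periodogram oracle on the resampled series
  rrB <- mkRr(0.1, a = 0.04, a2 = 0.04, f2 = 0.3)
  hB <- hrvTable(lombScargleHrv(rrB, duration = 120))
  expect_true(all(abs(hB$lfhf - 1) < 0.25))
  bt <- beatTimes(rrB)
  tt <- seq(0.85, 119.6, by = 0.25)
  densePeak <- function(y) {                    # spline-resampled FFT peak
    yI <- spline(bt[-1], y, xout = tt)$y
    yI <- yI - mean(yI)
    P <- Mod(fft(yI))^2
    f <- (seq_along(P) - 1) / (length(P) * 0.25)
    function(f0) max(P[abs(f - f0) < 0.02])
  }
  pAt <- densePeak(diff(bt) * 1000)
  # calibrate the resampling attenuation with pure tones on the same grid
  cal1 <- densePeak(sin(2 * pi * 0.1 * bt[-1]))(0.1)
  cal2 <- densePeak(sin(2 * pi * 0.3 * bt[-1]))(0.3)
  expect_lt(abs((pAt(0.1) / cal1) / (pAt(0.3) / cal2) - 1), 0.3)
})

test_that("HRV windows have 1/T resolution and flag sparse windows", {
  hrv <- lombScargleHrv(new("RRSeries",
                            beatTimes = cumsum(c(0, rep(0.8, 80))),
                            correctedFlags = logical(80)), duration = 90)
  expect_equal(frequencyResolution(hrv), 1 / 30)
  w <- hrvTable(hrv)
  expect_equal(nrow(w), 3)
  sparse <- lombScargleHrv(new("RRSeries", beatTimes = c(0, 10, 20, 29),
                               correctedFlags = logical(3)), duration = 30)
  expect_true(all(hrvTable(sparse)$missing))
})

test_that("Lomb-Scargle agrees with the FFT periodogram on even sampling", {
  set.seed(4)
  fs0 <- 4
  t <- seq(0, 63.75, by = 1 / fs0)
  y <- sin(2 * pi * 0.3 * t) + 0.5 * sin(2 * pi * 0.11 * t) + rnorm(length(t), 0, 0.1)
  fGrid <- seq(1 / length(t) / (1 / fs0), fs0 / 2 - 0.05, by = 1 / 64)
  ls <- lombScargle(t, y, fGrid)
  P <- Mod(fft(y - mean(y)))^2
  fF <- (seq_along(P) - 1) * fs0 / length(P)
  half <- fF > 0 & fF < fs0 / 2
  expect_lt(abs(fGrid[which.max(ls)] - fF[half][which.max(P[half])]), 1 / 64 + 1e-9)
})

test_that("estimated LF/HF tracks the generator truth across a session", {
  s1 <- singleSubject720()
  est <- hrvTable(s1$hrv)$lfhf
  tru <- s1$truth@trueLfHf$lfhf
  ok <- !is.na(est)
  expect_gte(cor(est[ok], tru[ok]), 0.8)
})
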