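# ECG beat detection and heart-rate-variability spectra: QRS-band filtering,
# Pan-Tompkins detection with adaptive thresholds, local-median RR artifact
# correction, and windowed Lomb-Scargle LF/HF estimation on the unevenly
# sampled RR series.

#' Band-pass filter ECG for QRS emphasis
#'
#' Butterworth high-pass/low-pass pair applied forward-backward; the default
#' 5-20 Hz band rejects baseline drift and mains interference while keeping
#' the QRS energy band.
#'
#' @param x numeric ECG vector.
#' @param fs sampling rate, Hz (must exceed 40 Hz).
#' @param low,high cut-off frequencies, Hz.
#' @param order filter order per pass.
#' @return filtered signal.
#' @export
bandpassEcg <- function(x, fs, low = 5, high = 20, order = 5) {
  if (fs <= 40) stop("sampling rate must exceed 40 Hz")
  if (low <= 0 || high <= low || high >= fs / 2) stop("invalid band edges")
  x <- butterFiltfilt(x, fs, low, "high", order)
  butterFiltfilt(x, fs, high, "low", order)
}

#' Detect R peaks (Pan-Tompkins)
#'
#' The classical chain: five-point derivative, squaring, 150-ms moving-window
#' integration, then dual adaptive thresholds on the integrated signal with
#' search-back at half threshold when a beat is overdue. Candidates within
#' the 200-ms refractory period are ignored, and a candidate arriving within
#' 360 ms of the previous beat is rejected as a T wave when its maximal
#' integrated-signal slope is less than half that of the previous beat. Each
#' accepted candidate is refined to the maximum of the filtered ECG within
#' +/-150 ms.
#'
#' @param x band-pass filtered ECG (see [bandpassEcg()]).
#' @param fs sampling rate, Hz.
#' @return an [RRSeries-class]; empty (with a warning) when no beats are
#'   found.
#' @export
detectRPeaks <- function(x, fs) {
  if (length(x) / fs < 10) stop("need at least 10 s of signal")
  # derivative -> squaring -> moving integration
  n <- length(x)
  d <- numeric(n)
  d[5:n] <- (2 * x[5:n] + x[4:(n - 1)] - x[2:(n - 3)] - 2 * x[1:(n - 4)]) / 8
  sq <- d^2
  Nw <- max(1L, round(0.15 * fs))
  integ <- stats::filter(sq, rep(1 / Nw, Nw), sides = 1)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  # candidate peaks: local maxima of the integrated signal
  isPk <- integ > c(-Inf, integ[-n]) & integ >= c(integ[-1], -Inf) & integ > 0
  cand <- which(isPk)
  if (!length(cand)) {
    warning("no R peaks found")
    return(new("RRSeries", beatTimes = numeric(), correctedFlags = logical()))
  }
  refr <- round(0.2 * fs)
  twin <- round(0.36 * fs)

  init <- integ[seq_len(min(n, 2 * fs))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  thr1 <- npki + 0.25 * (spki - npki)

  slopeAt <- function(i) {
    lo <- max(1L, i - round(0.075 * fs))
    max(diff(integ[lo:i]), 0)
  }

  beats <- integer()
  beatSlope <- numeric()
  rrAvg <- NA_real_
  lastBeat <- -Inf
  ci <- 1L
  while (ci <= length(cand)) {
    i <- cand[ci]
    pk <- integ[i]
    if (i - lastBeat < refr) { ci <- ci + 1L; next }
    accept <- FALSE
    if (pk > thr1) {
      accept <- TRUE
      if (is.finite(lastBeat) && (i - lastBeat) < twin && length(beats)) {
        if (slopeAt(i) < 0.5 * beatSlope[length(beatSlope)]) accept <- FALSE
      }
    }
    if (accept) {
      beats <- c(beats, i)
      beatSlope <- c(beatSlope, slopeAt(i))
      spki <- 0.125 * pk + 0.875 * spki
      if (length(beats) > 1) {
        rr <- diff(tail(beats, 9))
        rrAvg <- mean(rr)
      }
      lastBeat <- i
    } else {
      npki <- 0.125 * pk + 0.875 * npki
      # search-back: no beat for 1.66 x the running RR average
      if (!is.na(rrAvg) && (i - lastBeat) > 1.66 * rrAvg) {
        win <- cand[cand > lastBeat + refr & cand <= i]
        if (length(win)) {
          j <- win[which.max(integ[win])]
          if (integ[j] > 0.5 * thr1) {
            beats <- sort(c(beats, j))
            beatSlope <- c(beatSlope, slopeAt(j))
            spki <- 0.25 * integ[j] + 0.75 * spki
            lastBeat <- max(beats)
          }
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
    ci <- ci + 1L
  }
  if (!length(beats)) {
    warning("no R peaks found")
    return(new("RRSeries", beatTimes = numeric(), correctedFlags = logical()))
  }
  # refine to the filtered-ECG maximum near each integration peak
  half <- round(0.15 * fs)
  rIdx <- vapply(beats, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  rIdx <- sort(unique(rIdx))
  # drop refinements collapsing below the refractory period
  keep <- c(TRUE, diff(rIdx) >= refr)
  rIdx <- rIdx[keep]
  new("RRSeries", beatTimes = (rIdx - 1) / fs,
      correctedFlags = logical(max(0L, length(rIdx) - 1L)))
}

#' Correct ectopic/artifact RR intervals
#'
#' An interval deviating from its local median (window of `window` beats) by
#' more than the fraction `tol` is flagged and replaced by cubic-spline
#' interpolation of the surrounding clean intervals over beat time. Beat
#' times are rebuilt from the corrected intervals, anchored at the first
#' beat.
#'
#' @param rrSeries an [RRSeries-class] with at least 6 beats.
#' @param tol relative deviation tolerance.
#' @param window local-median window (odd number of intervals).
#' @return an [RRSeries-class] with `correctedFlags` marking replacements.
#' @export
correctRr <- function(rrSeries, tol = 0.2, window = 11) {
  stopifnot(is(rrSeries, "RRSeries"))
  bt <- beatTimes(rrSeries)
  rr <- diff(bt)
  if (length(rr) < 5) stop("need at least 5 RR intervals")
  window <- min(window, length(rr) - (1 - length(rr) %% 2))
  med <- stats::runmed(rr, k = max(3, window), endrule = "median")
  flag <- abs(rr - med) > tol * med
  if (mean(flag) > 0.5) stop("unreliable RR: more than half the intervals flagged")
  if (any(flag)) {
    tMid <- (bt[-1] + bt[-length(bt)]) / 2
    sf <- stats::splinefun(tMid[!flag], rr[!flag], method = "natural")
    rr[flag] <- sf(tMid[flag])
    bt <- bt[1] + cumsum(c(0, rr))
  }
  new("RRSeries", beatTimes = bt, correctedFlags = flag)
}

#' Lomb-Scargle periodogram for unevenly sampled data
#'
#' Classical Lomb-Scargle power at the requested frequencies, computed on the
#' mean-removed values without resampling or detrending. Power is returned in
#' the squared units of `y` (variance scale).
#'
#' @param t sample times, seconds.
#' @param y sample values.
#' @param freqs frequencies to evaluate, Hz.
#' @return numeric power at each frequency.
#' @export
lombScargle <- function(t, y, freqs) {
  y <- y - mean(y)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    arg <- w * (t - tau)
    ct <- cos(arg); st <- sin(arg)
    0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
  }, numeric(1))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Windowed LF/HF heart-rate-variability features
#'
#' For each window the Lomb-Scargle periodogram of the (beat time, RR) points
#' is evaluated on a grid covering 0.04-0.4 Hz whose fundamental resolution
#' is `1/window` (0.033 Hz for 30-s windows), oversampled by `oversample`.
#' LF (0.04-0.15 Hz) and HF (0.15-0.4 Hz) powers integrate the grid by the
#' trapezoid rule; `lfhf` is their ratio. Windows holding fewer than
#' `minBeats` beats are marked missing.
#'
#' @param rrSeries an [RRSeries-class].
#' @param window,step window length and step, seconds.
#' @param oversample frequency-grid oversampling factor.
#' @param minBeats minimum beats per window.
#' @param duration session duration in seconds; defaults to the last beat.
#' @return an [HRVWindows-class]; RR power is in ms^2-scale units.
#' @export
lombScargleHrv <- function(rrSeries, window = 30, step = 30, oversample = 4,
                           minBeats = 10, duration = NULL) {
  stopifnot(is(rrSeries, "RRSeries"))
  bt <- beatTimes(rrSeries)
  if (is.null(duration)) duration <- if (length(bt)) max(bt) else 0
  startsW <- seq(0, max(0, duration - window), by = step)
  res <- 1 / window
  df <- res / oversample
  freqs <- seq(0.04, 0.4, by = df)
  lfSel <- freqs < 0.15
  rrAll <- diff(bt) * 1000                     # ms
  tMid <- if (length(bt) > 1) bt[-1] else numeric()
  rows <- lapply(startsW, function(w0) {
    sel <- tMid >= w0 & tMid < w0 + window
    nb <- sum(sel)
    if (nb < minBeats)
      return(data.frame(windowStart = w0, hrMean = NA_real_, lf = NA_real_,
                        hf = NA_real_, lfhf = NA_real_, nBeats = nb,
                        missing = TRUE))
    p <- lombScargle(tMid[sel], rrAll[sel], freqs)
    lf <- trapz(freqs[lfSel], p[lfSel])
    hf <- trapz(freqs[!lfSel], p[!lfSel])
    data.frame(windowStart = w0, hrMean = 60000 / mean(rrAll[sel]),
               lf = lf, hf = hf,
               lfhf = if (hf > 0) lf / hf else NA_real_,
               nBeats = nb, missing = FALSE)
  })
  new("HRVWindows", windows = do.call(rbind, rows),
      window = window, step = step, resolution = res)
}
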