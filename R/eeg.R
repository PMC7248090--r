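# EEG preprocessing and spectral features: band-pass filtering, blink
# correction on the Fpz channel, 2-s/0.125-s epoching, three-criterion
# artifact rejection, Hanning periodograms and IAF-anchored band powers.

butterFiltfilt <- function(x, fs, cutoff, type, order) {
  flt <- signal::butter(order, cutoff / (fs / 2), type)
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) out[i, ] <- signal::filtfilt(flt, x[i, ])
    out
  } else signal::filtfilt(flt, x)
}

#' Band-pass filter EEG
#'
#' Butterworth high-pass then low-pass of the given order, each applied
#' forward-backward so the net phase shift is zero and epoch features stay
#' aligned with the session timeline.
#'
#' @param x numeric vector or channels x samples matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param low,high cut-off frequencies, Hz.
#' @param order filter order (per pass).
#' @return filtered signal, same shape as `x`.
#' @export
bandpassEeg <- function(x, fs, low = 1, high = 40, order = 5) {
  if (high >= fs / 2) stop("high cut-off must be below the Nyquist frequency")
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  x <- butterFiltfilt(x, fs, low, "high", order)
  butterFiltfilt(x, fs, high, "low", order)
}

#' Remove eye-blink contributions using the Fpz channel
#'
#' Blink intervals are detected on the Fpz channel after 0.5-6 Hz band-pass
#' filtering by an amplitude threshold; each detected interval is padded and
#' merged with overlapping neighbours. Within an interval, the blink
#' waveform is taken to be the baseline-detrended Fpz segment, and every
#' channel is corrected by subtracting its least-squares-scaled copy of that
#' waveform. Samples outside blink intervals are untouched, so no data is
#' lost to the correction.
#'
#' @param eeg channels x samples matrix with row names.
#' @param fs sampling rate, Hz.
#' @param fpzLabel name of the blink reference channel.
#' @param threshold detection threshold on the band-passed Fpz, microvolts.
#' @param pad padding added to each side of a detected interval, seconds.
#' @param allowMissing if `TRUE`, a missing reference channel produces a
#'   warning and the input is returned unchanged; otherwise it is an error.
#' @return corrected matrix with attribute `blinkIntervals`
#'   (`data.frame(start, end)` in seconds).
#' @export
correctBlinks <- function(eeg, fs, fpzLabel = "Fpz", threshold = 50,
                          pad = 0.15, allowMissing = FALSE) {
  if (!fpzLabel %in% rownames(eeg)) {
    if (allowMissing) {
      warning("channel '", fpzLabel, "' not found; blink correction skipped")
      attr(eeg, "blinkIntervals") <- data.frame(start = numeric(), end = numeric())
      return(eeg)
    }
    stop("channel '", fpzLabel, "' not found")
  }
  fpz <- eeg[fpzLabel, ]
  fpzBand <- butterFiltfilt(butterFiltfilt(fpz, fs, 0.5, "high", 4),
                            fs, 6, "low", 4)
  above <- fpzBand > threshold
  if (!any(above)) {
    attr(eeg, "blinkIntervals") <- data.frame(start = numeric(), end = numeric())
    return(eeg)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  padN <- round(pad * fs)
  iv[, 1] <- pmax(1L, iv[, 1] - padN)
  iv[, 2] <- pmin(length(fpz), iv[, 2] + padN)
  # merge overlapping intervals
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (j in 2:nrow(iv)) {
    if (iv[j, 1] <= merged[nrow(merged), 2] + 1L)
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[j, 2])
    else merged <- rbind(merged, iv[j, , drop = FALSE])
  }
  for (j in seq_len(nrow(merged))) {
    idx <- merged[j, 1]:merged[j, 2]
    seg <- fpz[idx]
    base <- seq(seg[1], seg[length(seg)], length.out = length(seg))
    w <- seg - base                      # blink waveform, baseline-detrended
    ww <- sum(w * w)
    if (ww < .Machine$double.eps) next
    beta <- as.vector(eeg[, idx, drop = FALSE] %*% w) / ww
    eeg[, idx] <- eeg[, idx] - beta %o% w
  }
  attr(eeg, "blinkIntervals") <- data.frame(start = (merged[, 1] - 1) / fs,
                                            end = (merged[, 2] - 1) / fs)
  eeg
}

#' Segment a signal into moving-window epochs
#'
#' Epochs of `win` seconds advancing by `shift` seconds, referenced by start
#' sample against the stored signal (half-open sample ranges). A signal of
#' duration `T` yields `floor((T - win)/shift) + 1` epochs.
#'
#' @param x channels x samples matrix (a vector is treated as one channel).
#' @param fs sampling rate, Hz.
#' @param win,shift window length and shift, seconds.
#' @return an [EpochSet-class].
#' @export
epochSignal <- function(x, fs, win = 2, shift = 0.125) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  nSamp <- ncol(x)
  if (nSamp / fs < win) stop("signal shorter than one window")
  L <- round(win * fs)
  step <- shift * fs
  if (abs(step - round(step)) > 1e-9)
    stop("shift must be an integer number of samples at this rate")
  step <- as.integer(round(step))
  starts <- seq.int(1L, nSamp - L + 1L, by = step)
  new("EpochSet", signal = x, fs = fs, win = win, shift = shift,
      startSamples = as.integer(starts),
      mask = data.frame())
}

#' Flag artifact epochs by amplitude, trend and sample-to-sample criteria
#'
#' An epoch is flagged `threshold` when any sample on any channel exceeds
#' `ampThr` in absolute value, `trend` when the least-squares slope of any
#' channel exceeds `slopeThr`, and `sampleToSample` when any adjacent-sample
#' absolute difference exceeds `diffThr`. Flagged epochs are excluded from
#' spectral features downstream.
#'
#' @param epochs an [EpochSet-class].
#' @param ampThr amplitude threshold, microvolts.
#' @param slopeThr trend threshold, microvolts per second.
#' @param diffThr sample-to-sample threshold, microvolts.
#' @return the `EpochSet` with its artifact mask filled in; see
#'   [artifactMask()].
#' @export
flagArtifacts <- function(epochs, ampThr = 100, slopeThr = 10, diffThr = 25) {
  stopifnot(is(epochs, "EpochSet"))
  if (any(c(ampThr, slopeThr, diffThr) <= 0)) stop("thresholds must be positive")
  L <- round(epochs@win * epochs@fs)
  k <- (seq_len(L) - 1) / epochs@fs
  kc <- k - mean(k)
  sxx <- sum(kc^2)
  n <- length(epochs@startSamples)
  thr <- trend <- s2s <- logical(n)
  sig <- epochs@signal
  for (e in seq_len(n)) {
    s <- epochs@startSamples[e]
    seg <- sig[, s:(s + L - 1L), drop = FALSE]
    thr[e] <- max(abs(seg)) > ampThr
    slopes <- (seg %*% kc) / sxx
    trend[e] <- max(abs(slopes)) > slopeThr
    s2s[e] <- max(abs(seg[, -1L, drop = FALSE] - seg[, -L, drop = FALSE])) > diffThr
  }
  epochs@mask <- data.frame(flagged = thr | trend | s2s,
                            threshold = thr, trend = trend,
                            sampleToSample = s2s)
  validObject(epochs)
  epochs
}

#' Per-epoch power spectral density
#'
#' One-sided single-taper periodogram per clean epoch and channel, using a
#' Hanning taper of the full epoch length; for 2-s epochs the bin spacing is
#' 0.5 Hz. Flagged epochs are skipped.
#'
#' @param epochs an [EpochSet-class] (run [flagArtifacts()] first to exclude
#'   artifacts; an empty mask means every epoch is used).
#' @param maxFreq highest frequency bin retained, Hz.
#' @return a [SpectralFeatures-class] with the PSD array filled in
#'   (microvolt^2/Hz).
#' @export
computePsd <- function(epochs, maxFreq = 40) {
  stopifnot(is(epochs, "EpochSet"))
  keep <- if (nrow(epochs@mask)) which(!epochs@mask$flagged)
          else seq_along(epochs@startSamples)
  if (!length(keep)) stop("no clean epochs")
  fs <- epochs@fs
  L <- round(epochs@win * fs)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))   # Hanning
  U <- sum(w^2)
  freqs <- (0:(L %/% 2)) * fs / L
  fKeep <- which(freqs <= maxFreq + 1e-9)
  nCh <- nrow(epochs@signal)
  psd <- array(0, c(length(keep), nCh, length(fKeep)))
  scale1 <- 1 / (fs * U)
  dbl <- ifelse(fKeep == 1L | freqs[fKeep] >= fs / 2 - 1e-9, 1, 2)
  sig <- epochs@signal
  for (j in seq_along(keep)) {
    s <- epochs@startSamples[keep[j]]
    seg <- sig[, s:(s + L - 1L), drop = FALSE]
    X <- stats::mvfft(t(seg) * w)
    P <- (Mod(X[fKeep, , drop = FALSE])^2) * scale1 * dbl
    psd[j, , ] <- t(P)
  }
  dimnames(psd) <- list(NULL, rownames(sig), NULL)
  new("SpectralFeatures", psd = psd, freqs = freqs[fKeep],
      epochStart = (epochs@startSamples[keep] - 1L) / fs,
      iaf = NA_real_, bandEdges = list(), bandPower = array(0, c(0, 0, 0)))
}

#' Estimate the individual alpha frequency
#'
#' Averages the Hanning-taper PSD of the eyes-closed baseline over 2-s
#' epochs and the parieto-occipital channels, then returns the frequency of
#' the spectral maximum within the alpha search window. When the maximum is
#' not a clear local peak (prominence below `minProminence` times the
#' in-window median, or sitting on the window edge), the conventional 10 Hz
#' is returned and the `peakFound` attribute is set to `FALSE` with a
#' warning.
#'
#' @param ocBaseline channels x samples matrix: eyes-closed EEG of at least
#'   30 s.
#' @param fs sampling rate, Hz.
#' @param channels channels to average; defaults to the parieto-occipital
#'   sites present in the data.
#' @param searchRange alpha search window, Hz.
#' @param minProminence peak-to-median ratio required to accept a peak.
#' @return IAF in Hz with attribute `peakFound`.
#' @export
estimateIaf <- function(ocBaseline, fs, channels = NULL,
                        searchRange = c(7, 13), minProminence = 1.5) {
  if (!is.matrix(ocBaseline)) ocBaseline <- matrix(ocBaseline, nrow = 1)
  if (ncol(ocBaseline) / fs < 30) stop("baseline must be at least 30 s")
  if (is.null(channels)) {
    po <- c("Pz", "P3", "P4", "POz", "PO3", "PO4", "O1", "O2")
    channels <- intersect(po, rownames(ocBaseline))
    if (!length(channels)) channels <- rownames(ocBaseline)
    if (is.null(channels)) channels <- seq_len(nrow(ocBaseline))
  }
  eps <- epochSignal(ocBaseline[channels, , drop = FALSE], fs,
                     win = 2, shift = 0.25)
  sp <- computePsd(eps, maxFreq = fs / 2)
  avg <- apply(psdArray(sp), 3, mean)
  f <- psdFrequencies(sp)
  inWin <- which(f >= searchRange[1] & f <= searchRange[2])
  pk <- inWin[which.max(avg[inWin])]
  edge <- pk == inWin[1] || pk == inWin[length(inWin)]
  prominent <- avg[pk] >= minProminence * median(avg[inWin])
  localMax <- pk > 1 && pk < length(avg) && avg[pk] >= avg[pk - 1] &&
    avg[pk] >= avg[pk + 1]
  if (edge || !prominent || !localMax) {
    warning("no clear alpha peak in the baseline; falling back to 10 Hz")
    return(structure(10, peakFound = FALSE))
  }
  structure(f[pk], peakFound = TRUE)
}

#' IAF-anchored band edges
#'
#' The band convention used throughout: theta `[iaf-6, iaf-2)`, alpha
#' `[iaf-2, iaf+2)`, beta `[iaf+2, iaf+16)`, gamma `[iaf+16, upper]`.
#'
#' @param iaf individual alpha frequency, Hz.
#' @param offsets band offsets relative to the IAF.
#' @param upper gamma upper edge, Hz.
#' @return named list of `c(low, high)` per band.
#' @export
iafBandEdges <- function(iaf, offsets = c(-6, -2, 2, 16), upper = 40) {
  list(theta = c(iaf + offsets[1], iaf + offsets[2]),
       alpha = c(iaf + offsets[2], iaf + offsets[3]),
       beta = c(iaf + offsets[3], iaf + offsets[4]),
       gamma = c(iaf + offsets[4], upper))
}

#' Band powers from per-epoch spectra
#'
#' Mean PSD over the frequency bins of each IAF-anchored band. Bands are
#' half-open on the right except gamma, which includes its upper edge.
#'
#' @param spectral a [SpectralFeatures-class] from [computePsd()].
#' @param iaf individual alpha frequency in Hz, from [estimateIaf()].
#' @param offsets,upper band convention, see [iafBandEdges()].
#' @return the `SpectralFeatures` with `bandPower` (epochs x channels x 4)
#'   and `bandEdges` filled in.
#' @export
bandPowers <- function(spectral, iaf, offsets = c(-6, -2, 2, 16), upper = 40) {
  stopifnot(is(spectral, "SpectralFeatures"))
  if (iaf < 7 || iaf > 13) stop("iaf must lie in [7, 13] Hz")
  edges <- iafBandEdges(iaf, offsets, upper)
  f <- spectral@freqs
  d <- dim(spectral@psd)
  bp <- array(0, c(d[1], d[2], length(edges)),
              dimnames = list(NULL, dimnames(spectral@psd)[[2]], names(edges)))
  for (b in seq_along(edges)) {
    lo <- edges[[b]][1]; hi <- edges[[b]][2]
    sel <- if (names(edges)[b] == "gamma") f >= lo - 1e-9 & f <= hi + 1e-9
           else f >= lo - 1e-9 & f < hi - 1e-9
    if (!any(sel)) stop("band '", names(edges)[b], "' contains no frequency bins")
    bp[, , b] <- apply(spectral@psd[, , sel, drop = FALSE], c(1, 2), mean)
  }
  spectral@iaf <- iaf
  spectral@bandEdges <- edges
  spectral@bandPower <- bp
  validObject(spectral)
  spectral
}
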