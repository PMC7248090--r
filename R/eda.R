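# Electrodermal activity: anti-aliased downsampling, continuous
# decomposition of skin conductance into tonic and phasic components by
# regularized deconvolution with a biexponential impulse response, and 5-s
# windowed SCL/SCR features.

#' Downsample skin conductance
#'
#' Anti-alias low-pass (Butterworth, cut-off at 40% of the output rate,
#' forward-backward) followed by decimation.
#'
#' @param x numeric conductance vector, microsiemens.
#' @param fsIn,fsOut input and output sampling rates; `fsIn` must be an
#'   integer multiple of `fsOut`.
#' @return downsampled signal of length `ceiling(length(x)/ratio)`.
#' @export
downsampleGsr <- function(x, fsIn = 100, fsOut = 25) {
  ratio <- fsIn / fsOut
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("fsIn must be an integer multiple of fsOut")
  ratio <- as.integer(round(ratio))
  xf <- butterFiltfilt(x, fsIn, 0.8 * fsOut / 2, "low", 8)
  xf[seq.int(1L, length(x), by = ratio)]
}

# Gaussian smoothing with edge renormalisation.
gaussSmooth <- function(x, fs, sd_s) {
  if (sd_s <= 0) return(x)
  r <- ceiling(3 * sd_s * fs)
  k <- stats::dnorm(seq(-r, r), sd = sd_s * fs)
  k <- k / sum(k)
  num <- stats::convolve(x, rev(k), type = "open")
  den <- stats::convolve(rep(1, length(x)), rev(k), type = "open")
  (num / den)[(r + 1):(r + length(x))]
}

#' Continuous decomposition of skin conductance
#'
#' Deconvolves the (Gaussian-smoothed) conductance with the biexponential
#' impulse response `b(t) = exp(-t/tauDecay) - exp(-t/tauRise)` by Tikhonov-
#' regularized division in the frequency domain; the regularisation weight is
#' picked by the discrepancy principle as the largest weight whose
#' reconstruction error stays below `tol` (relative L2). The driver is split
#' into a smooth inter-impulse tonic driver (running low quantile between
#' impulses, interpolated and smoothed) and the remaining phasic driver;
#' `tonic` is the tonic driver convolved back with the impulse response and
#' `phasic` is the residual `sc - tonic`, floored at `-floorTol`.
#'
#' @param sc skin conductance at `fs`, microsiemens, at least 60 s.
#' @param fs sampling rate, Hz.
#' @param tauRise,tauDecay impulse-response time constants, seconds.
#' @param smoothSd pre-smoothing Gaussian width, seconds.
#' @param tol discrepancy tolerance (relative reconstruction error).
#' @param floorTol negative tolerance allowed in the phasic component.
#' @return an [EDADecomposition-class]; attribute `reconError` holds the
#'   relative reconstruction error of `driver * irf` against the smoothed
#'   input.
#' @export
cdaDecompose <- function(sc, fs = 25, tauRise = 1, tauDecay = 3.75,
                         smoothSd = 1, tol = 0.02, floorTol = 0.02) {
  if (tauDecay <= tauRise || tauRise <= 0)
    stop("need tauDecay > tauRise > 0")
  if (length(sc) / fs < 60) stop("need at least 60 s of skin conductance")
  if (max(sc) <= 0) stop("conductance must be positive somewhere")
  nOrig <- length(sc)
  scs <- gaussSmooth(sc, fs, smoothSd)

  kern <- batemanKernel(fs, tauRise, tauDecay)
  kl <- length(kern)
  # constant padding absorbs the onset transient of the deconvolution
  padded <- c(rep(scs[1], kl), scs, rep(scs[nOrig], kl))
  nTot <- stats::nextn(length(padded) + kl)
  B <- fft(c(kern, rep(0, nTot - kl)))
  S <- fft(c(padded, rep(0, nTot - length(padded))))
  b2 <- Mod(B)^2
  deconvAt <- function(lambda) {
    d <- Re(fft(S * Conj(B) / (b2 + lambda), inverse = TRUE)) / nTot
    d[seq_along(padded)]
  }
  reconOf <- function(d) {
    r <- stats::convolve(d, rev(kern), type = "open")[seq_along(d)]
    r[(kl + 1):(kl + nOrig)]
  }
  lamGrid <- max(b2) * 10^seq(-8, -1, by = 0.5)
  driver <- NULL
  for (lam in rev(lamGrid)) {        # largest acceptable weight wins
    d <- deconvAt(lam)
    err <- sqrt(sum((reconOf(pmax(d, 0)) - scs)^2) / sum(scs^2))
    if (err <= tol) { driver <- d; break }
  }
  if (is.null(driver)) driver <- deconvAt(lamGrid[1])
  driver <- pmax(driver, 0)

  # running window summaries on a coarse grid, interpolated back
  runningStat <- function(x, stat, half_s = 5) {
    gridStep <- max(1L, round(2 * fs))
    centers <- seq(1L, length(x), by = gridStep)
    half <- round(half_s * fs)
    level <- vapply(centers, function(i) {
      lo <- max(1L, i - half); hi <- min(length(x), i + half)
      stat(x[lo:hi])
    }, numeric(1))
    stats::approx(centers, level, xout = seq_along(x), rule = 2)$y
  }
  # tonic driver: running trough (10th percentile) of the ripple-smoothed
  # driver — insensitive to impulse bumps; its small downward bias is a
  # near-constant offset that the final baseline trim absorbs
  tonicDriver <- runningStat(gaussSmooth(driver, fs, 2),
                             function(w) as.numeric(quantile(w, 0.1)))
  tonicDriver <- gaussSmooth(tonicDriver, fs, 4)
  tonicDriver <- pmin(tonicDriver, driver + 1e-9)

  tonicFull <- stats::convolve(tonicDriver, rev(kern),
                               type = "open")[seq_along(tonicDriver)]
  idx <- (kl + 1):(kl + nOrig)
  tonic <- tonicFull[idx]
  # baseline trim: regularisation shrinks the deconvolution slightly, so the
  # running trough level (10th percentile) of the residual — the
  # inter-impulse floor, insensitive to phasic bumps — is folded back into
  # the tonic
  tonic <- tonic + runningStat(scs - tonic,
                               function(w) as.numeric(quantile(w, 0.1)),
                               half_s = 10)
  phasic <- pmax(scs - tonic, -floorTol)
  out <- new("EDADecomposition",
             time = (seq_len(nOrig) - 1) / fs, fs = fs, sc = scs,
             tonic = tonic, phasic = phasic,
             driver = (driver - tonicDriver)[idx],
             tauRise = tauRise, tauDecay = tauDecay)
  attr(out, "reconError") <-
    sqrt(sum((reconOf(driver) - scs)^2) / sum(scs^2))
  out
}

#' Detect phasic driver impulses
#'
#' The deconvolution spreads each impulse over roughly a second, so an
#' impulse's amplitude lives in the *integrated mass* of the phasic driver
#' around a local maximum, not in the peak height. Local maxima of the
#' lightly smoothed driver are located, maxima closer than `minGap` are
#' merged (keeping the larger), and each candidate's amplitude is the driver
#' mass within `halfWindow` seconds (truncated halfway to the neighbouring
#' candidate); candidates below `minAmplitude` are discarded.
#'
#' @param decomposition an [EDADecomposition-class].
#' @param minAmplitude detection threshold on the integrated driver mass
#'   (microsiemens).
#' @param minGap minimum separation between impulses, seconds.
#' @param halfWindow integration half-window, seconds.
#' @return `data.frame(time, amplitude)`.
#' @export
detectScrImpulses <- function(decomposition, minAmplitude = 0.05, minGap = 1,
                              halfWindow = 3) {
  d0 <- driverSignal(decomposition)
  fs <- decomposition@fs
  d <- gaussSmooth(pmax(d0, 0), fs, 0.3)
  n <- length(d)
  hThr <- minAmplitude / (4 * fs)             # height floor for a mass spread
  isPk <- d > c(-Inf, d[-n]) & d >= c(d[-1], -Inf) & d > hThr
  pk <- which(isPk)
  if (!length(pk))
    return(data.frame(time = numeric(), amplitude = numeric()))
  if (length(pk) > 1) {                       # merge close maxima
    keep <- rep(TRUE, length(pk))
    last <- 1L
    for (j in 2:length(pk)) {
      if ((pk[j] - pk[last]) / fs < minGap) {
        if (d[pk[j]] > d[pk[last]]) { keep[last] <- FALSE; last <- j }
        else keep[j] <- FALSE
      } else last <- j
    }
    pk <- pk[keep]
  }
  halfN <- round(halfWindow * fs)
  mass <- vapply(seq_along(pk), function(j) {
    lo <- pk[j] - halfN; hi <- pk[j] + halfN
    if (j > 1) lo <- max(lo, ceiling((pk[j - 1] + pk[j]) / 2))
    if (j < length(pk)) hi <- min(hi, floor((pk[j] + pk[j + 1]) / 2))
    sum(d0[max(1L, lo):min(n, hi)])
  }, numeric(1))
  out <- data.frame(time = decomposition@time[pk], amplitude = mass)
  out[out$amplitude >= minAmplitude, , drop = FALSE]
}

#' Windowed tonic and phasic features
#'
#' Mean tonic (SCL) and mean phasic (SCR) conductance per non-overlapping
#' window.
#'
#' @param decomposition an [EDADecomposition-class].
#' @param window window length, seconds (5 s by convention).
#' @return `data.frame(windowStart, scl, scr)`.
#' @export
windowEda <- function(decomposition, window = 5) {
  fs <- decomposition@fs
  n <- length(decomposition@tonic)
  L <- round(window * fs)
  if (n < L) stop("decomposition shorter than one window")
  nW <- n %/% L
  starts <- (seq_len(nW) - 1L) * L + 1L
  data.frame(
    windowStart = (starts - 1L) / fs,
    scl = windowSums(decomposition@tonic, starts, L) / L,
    scr = windowSums(decomposition@phasic, starts, L) / L
  )
}
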