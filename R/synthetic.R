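# Synthetic multimodal session generator. The generator writes down the true
# value of every quantity the extractors later estimate (GroundTruth), which
# is what makes the whole pipeline testable without human recordings.

#' Default generator parameters
#'
#' Returns the parameter list consumed by [generateRecording()]. The defaults
#' describe a plausible resting operator whose frontal and parieto-occipital
#' EEG band amplitudes, LF/HF sympathovagal balance and tonic skin
#' conductance all rise during the medium- and high-stress slots and remain
#' partly elevated in the final slot (the transient after-effect the
#' analysis is designed to expose). Effect sizes are free parameters of the
#' simulation, not measurements.
#'
#' @param iaf simulated individual alpha frequency, Hz.
#' @param slotGain per-slot amplitude multiplier applied to the
#'   stress-responsive EEG channels in all four bands. `c(1, 1, 1, 1)`
#'   yields a null generator.
#' @param lfhfBySlot true LF/HF power ratio per slot.
#' @param sclBySlot tonic skin-conductance level per slot, microsiemens.
#' @param scrRateBySlot phasic driver impulse rate per slot, impulses/min.
#' @param meanHR mean heart rate, bpm.
#' @param rrModSd total fractional RR modulation (standard-deviation scale).
#' @param blinkRate eye-blink rate, blinks/s.
#' @param blinkAmplitude blink amplitude on Fpz, microvolts.
#' @param artifactRate injected non-blink EEG defect rate, defects/min.
#' @param eegNoiseSd 1/f background EEG standard deviation, microvolts.
#' @param ecgNoiseSd additive ECG noise, millivolts.
#' @param gsrNoiseSd additive skin-conductance noise, microsiemens.
#' @param tauRise,tauDecay electrodermal impulse-response constants, seconds.
#' @param stressChannels channels whose band amplitudes scale with
#'   `slotGain`; default frontal plus parieto-occipital, leaving `Cz` as a
#'   stress-silent control channel.
#' @return a named list of generator parameters.
#' @export
recordingParams <- function(iaf = 10,
                            slotGain = c(1, 1.15, 1.3, 1.25),
                            lfhfBySlot = c(1, 1.8, 3, 2.4),
                            sclBySlot = c(2, 2.3, 2.8, 2.6),
                            scrRateBySlot = c(4, 7, 10, 8),
                            meanHR = 70,
                            rrModSd = 0.05,
                            blinkRate = 0.2,
                            blinkAmplitude = 150,
                            artifactRate = 2,
                            eegNoiseSd = 8,
                            ecgNoiseSd = 0.02,
                            gsrNoiseSd = 0.005,
                            tauRise = 1, tauDecay = 3.75,
                            stressChannels = c("AFz", "AF3", "AF4", "Fz", "F3",
                                               "F4", "Pz", "P3", "P4", "POz",
                                               "PO3", "PO4", "O1", "O2")) {
  p <- as.list(environment())
  rates <- c(p$blinkRate, p$artifactRate, p$scrRateBySlot, p$meanHR)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (any(c(p$slotGain, p$lfhfBySlot, p$sclBySlot) < 0))
    stop("gains, ratios and levels must be non-negative")
  if (length(p$slotGain) != 4 || length(p$lfhfBySlot) != 4 ||
      length(p$sclBySlot) != 4 || length(p$scrRateBySlot) != 4)
    stop("per-slot parameters must have length 4")
  p
}

#' The standard 16-channel montage
#' @export
eegMontage <- function() {
  c("Fpz", "AFz", "AF3", "AF4", "Fz", "F3", "F4", "Cz",
    "Pz", "P3", "P4", "POz", "PO3", "PO4", "O1", "O2")
}

#' Default EEG feature channels
#'
#' The 14 channels entering the feature set: the full montage minus `Fpz`
#' (consumed by blink correction) and `AFz`.
#' @export
featureChannels <- function() setdiff(eegMontage(), c("Fpz", "AFz"))

# per-channel base oscillation amplitudes (uV) for the four rhythms
channelBandAmplitudes <- function(channels) {
  frontal <- c("Fpz", "AFz", "AF3", "AF4", "Fz", "F3", "F4")
  posterior <- c("Pz", "P3", "P4", "POz", "PO3", "PO4", "O1", "O2")
  amp <- matrix(0, length(channels), 4,
                dimnames = list(channels, c("theta", "alpha", "beta", "gamma")))
  amp[, "theta"] <- ifelse(channels %in% frontal, 3, 2)
  amp[, "alpha"] <- ifelse(channels %in% posterior, 6,
                           ifelse(channels %in% frontal, 2, 3))
  amp[, "beta"] <- 1.5
  amp[, "gamma"] <- 0.8
  amp
}

# blink propagation: strongest on Fpz, decaying toward posterior sites
blinkAttenuation <- function(channels) {
  prof <- c(Fpz = 1, AFz = 0.7, AF3 = 0.6, AF4 = 0.6, Fz = 0.45, F3 = 0.4,
            F4 = 0.4, Cz = 0.25, Pz = 0.12, P3 = 0.1, P4 = 0.1, POz = 0.07,
            PO3 = 0.07, PO4 = 0.07, O1 = 0.05, O2 = 0.05)
  out <- prof[channels]
  out[is.na(out)] <- 0.05
  unname(out)
}

# 400-ms positive half-sine blink pulse sampled at fs
blinkTemplate <- function(fs, amplitude = 150, duration = 0.4) {
  t <- seq(0, duration, by = 1 / fs)
  amplitude * sin(pi * t / duration)
}

# synthetic PQRST complex sampled at fs over +/- 0.35 s around the R peak
qrsTemplate <- function(fs) {
  t <- seq(-0.35, 0.45, by = 1 / fs)
  g <- function(a, mu, s) a * exp(-(t - mu)^2 / (2 * s^2))
  list(t = t,
       y = g(0.12, -0.2, 0.025) + g(-0.15, -0.025, 0.008) + g(1, 0, 0.01) +
           g(-0.2, 0.025, 0.008) + g(0.3, 0.25, 0.05))
}

# Integral pulse frequency modulation: beats fire when the integral of the
# instantaneous rate crosses successive integers. rateFun is evaluated on a
# fine grid; crossings are located by linear interpolation.
ipfmBeats <- function(duration, rateFun, dt = 0.05) {
  tt <- seq(0, duration, by = dt)
  rate <- rateFun(tt)
  cumInt <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  nBeats <- floor(cumInt[length(cumInt)])
  if (nBeats < 1) return(numeric())
  stats::approx(cumInt, tt, xout = seq_len(nBeats), ties = "ordered")$y
}

#' Generate a synthetic multimodal recording
#'
#' Simulates EEG (1/f background plus band oscillations, blinks and injected
#' amplitude/trend/jump defects), ECG (a PQRST train whose beat times come
#' from integral pulse frequency modulation of an instantaneous rate carrying
#' one low-frequency and one high-frequency oscillation), and skin
#' conductance (a smooth tonic curve plus Poisson phasic impulses convolved
#' with a biexponential impulse response), all tied to one [ScenarioTimeline-class].
#' The EEG stress response is an amplitude gain on the configured channels in
#' all four bands during the stress slots; the autonomic stress response is a
#' per-slot LF/HF ratio and tonic level.
#'
#' Everything stochastic is a pure function of `(timeline, params, seed)`.
#'
#' @param timeline a [ScenarioTimeline-class].
#' @param params generator parameters from [recordingParams()].
#' @param seed integer seed.
#' @return `list(recording = MultimodalRecording, truth = GroundTruth)`.
#' @examples
#' tl <- generateTimeline(720)
#' sim <- generateRecording(tl, seed = 1)
#' sim$recording
#' @export
generateRecording <- function(timeline, params = recordingParams(), seed = 1) {
  stopifnot(is(timeline, "ScenarioTimeline"))
  withSeed(seed, {
    fsEeg <- 256; fsEcg <- 256; fsGsr <- 100
    dur <- sessionDuration(timeline)
    sl <- slotTable(timeline)
    channels <- eegMontage()
    nCh <- length(channels)
    nEeg <- round(dur * fsEeg)
    tEeg <- (seq_len(nEeg) - 1) / fsEeg
    slotIdx <- findInterval(tEeg, sl$start)

    # --- EEG -------------------------------------------------------------
    bandFreq <- c(theta = params$iaf - 4, alpha = params$iaf,
                  beta = params$iaf + 9, gamma = params$iaf + 20)
    amp <- channelBandAmplitudes(channels)
    gainByCh <- matrix(1, nCh, 4)
    isStress <- channels %in% params$stressChannels
    gainT <- params$slotGain[slotIdx]      # amplitude gain over time
    eeg <- matrix(0, nCh, nEeg, dimnames = list(channels, NULL))
    for (ch in seq_len(nCh)) {
      x <- pinkNoise(nEeg, params$eegNoiseSd)
      for (b in seq_along(bandFreq)) {
        osc <- sin(2 * pi * bandFreq[b] * tEeg + runif(1, 0, 2 * pi))
        a <- amp[ch, b]
        if (isStress[ch]) osc <- osc * gainT
        x <- x + a * osc
      }
      eeg[ch, ] <- x
    }

    # blinks: Poisson with a 1-s refractory gap
    gaps <- 1 + stats::rexp(ceiling(dur * params$blinkRate * 2),
                            rate = params$blinkRate)
    blinkTimes <- cumsum(gaps)
    blinkTimes <- blinkTimes[blinkTimes < dur - 0.5]
    tpl <- blinkTemplate(fsEeg, params$blinkAmplitude)
    att <- blinkAttenuation(channels)
    for (bt in blinkTimes) {
      s <- round(bt * fsEeg) + 1L
      idx <- s:(s + length(tpl) - 1L)
      eeg[, idx] <- eeg[, idx] + att %o% tpl
    }

    # injected non-blink defects, one 2-s span each on a random channel
    nArt <- rpois(1, params$artifactRate * dur / 60)
    kinds <- c("step", "ramp", "jump")
    artifacts <- data.frame(start = numeric(), kind = character())
    if (nArt > 0) {
      starts <- sort(runif(nArt, 0, dur - 2.5))
      kind <- kinds[(seq_len(nArt) - 1L) %% 3L + 1L]
      for (j in seq_len(nArt)) {
        ch <- sample.int(nCh, 1)
        s <- round(starts[j] * fsEeg) + 1L
        span <- s:(s + 2L * fsEeg - 1L)
        if (kind[j] == "step") {
          eeg[ch, span] <- eeg[ch, span] + 120
        } else if (kind[j] == "ramp") {
          eeg[ch, span] <- eeg[ch, span] + 15 * (seq_along(span) - 1) / fsEeg
        } else {
          eeg[ch, s] <- eeg[ch, s] + 30
        }
      }
      artifacts <- data.frame(start = starts, kind = kind)
    }

    # eyes-closed baseline: prominent posterior alpha at the true IAF
    nOc <- 60L * fsEeg
    tOc <- (seq_len(nOc) - 1) / fsEeg
    posterior <- c("Pz", "P3", "P4", "POz", "PO3", "PO4", "O1", "O2")
    oc <- matrix(0, nCh, nOc, dimnames = list(channels, NULL))
    for (ch in seq_len(nCh)) {
      a <- if (channels[ch] %in% posterior) 8 else 2
      oc[ch, ] <- pinkNoise(nOc, 4) +
        a * sin(2 * pi * params$iaf * tOc + runif(1, 0, 2 * pi))
    }

    # --- ECG -------------------------------------------------------------
    T0 <- 60 / params$meanHR
    winStarts <- seq(0, dur - 30, by = 30)
    ratio <- params$lfhfBySlot[findInterval(winStarts, sl$start)]
    jitter <- exp(rnorm(length(winStarts), 0, 0.1))
    ratio <- ratio * jitter                       # per-window true LF/HF
    aHF <- params$rrModSd / sqrt(1 + ratio) * sqrt(2)
    aLF <- aHF * sqrt(ratio)
    phiL <- runif(1, 0, 2 * pi); phiH <- runif(1, 0, 2 * pi)
    ampAt <- function(t, a) a[pmin(length(a), findInterval(t, winStarts))]
    rateFun <- function(t) {
      m <- ampAt(t, aLF) * sin(2 * pi * 0.1 * t + phiL) +
           ampAt(t, aHF) * sin(2 * pi * 0.3 * t + phiH)
      (1 + m) / T0
    }
    beats <- ipfmBeats(dur, rateFun)
    tplQ <- qrsTemplate(fsEcg)
    nEcg <- round(dur * fsEcg)
    ecg <- rnorm(nEcg, 0, params$ecgNoiseSd)
    L <- length(tplQ$y)
    off <- round(tplQ$t[1] * fsEcg)
    for (bt in beats) {
      s <- round(bt * fsEcg) + 1L + off
      idx <- s:(s + L - 1L)
      keep <- idx >= 1L & idx <= nEcg
      ecg[idx[keep]] <- ecg[idx[keep]] + tplQ$y[keep]
    }
    trueLfHf <- data.frame(windowStart = winStarts, lfhf = aLF^2 / aHF^2)

    # --- GSR -------------------------------------------------------------
    nGsr <- round(dur * fsGsr)
    tGsr <- (seq_len(nGsr) - 1) / fsGsr
    ctrlT <- c(0, (sl$start + sl$end) / 2, dur)
    ctrlV <- c(params$sclBySlot[1], params$sclBySlot, params$sclBySlot[4])
    tonic <- stats::spline(ctrlT, ctrlV, xout = tGsr, method = "natural")$y
    scrT <- numeric(); scrA <- numeric()
    for (i in 1:4) {
      n <- rpois(1, params$scrRateBySlot[i] / 60 * (sl$end[i] - sl$start[i]))
      if (n > 0) {
        scrT <- c(scrT, sort(runif(n, sl$start[i], sl$end[i] - 1)))
        scrA <- c(scrA, rgamma(n, shape = 2, scale = 0.15))
      }
    }
    ord <- order(scrT); scrT <- scrT[ord]; scrA <- scrA[ord]
    impulses <- numeric(nGsr)
    impulses[pmin(nGsr, round(scrT * fsGsr) + 1L)] <- scrA
    kern <- batemanKernel(fsGsr, params$tauRise, params$tauDecay)
    phasic <- stats::convolve(impulses, rev(kern), type = "open")[seq_len(nGsr)]
    gsr <- tonic + phasic + rnorm(nGsr, 0, params$gsrNoiseSd)

    rec <- new("MultimodalRecording",
               eeg = eeg, eegRate = fsEeg, ecg = ecg, ecgRate = fsEcg,
               gsr = gsr, gsrRate = fsGsr, ocBaseline = oc, t0 = 0)
    keep <- seq(1, nGsr, by = 4)                 # truth tonic stored at 25 Hz
    truth <- new("GroundTruth",
                 rPeakTimes = beats, blinkTimes = blinkTimes,
                 scrImpulses = data.frame(time = scrT, amplitude = scrA),
                 artifactEpochs = artifacts,
                 tonicTime = tGsr[keep], tonic = tonic[keep],
                 trueLfHf = trueLfHf, slotGain = params$slotGain,
                 iaf = params$iaf, seed = as.integer(seed))
    list(recording = rec, truth = truth)
  })
}

#' Generate subjective ratings
#'
#' Simulates the 5-point operator (ATCO) and supervisor (SME) stress ratings
#' plus the supervisor's efficiency rating at the timeline's rating instants.
#' Stress ratings follow a per-slot mean profile that rises through the
#' medium- and high-stress slots and falls back in the final slot (the
#' underestimation of residual stress once events cease); efficiency follows
#' the mirrored declining profile. The ATCO-vs-SME sample correlation is
#' steered to `correlationTarget` by correlating the rating noise around the
#' shared profile (negatively when the shared profile alone would correlate
#' the two series more strongly than requested).
#'
#' @param timeline a [ScenarioTimeline-class].
#' @param correlationTarget target ATCO-vs-SME stress correlation in
#'   `[-1, 1]`.
#' @param seed integer seed.
#' @return a [SubjectiveRatings-class] object.
#' @export
generateRatings <- function(timeline, correlationTarget = 0.51, seed = 1) {
  if (!is.numeric(correlationTarget) || abs(correlationTarget) > 1)
    stop("correlationTarget must lie in [-1, 1]")
  withSeed(seed, {
    tms <- ratingTimes(timeline)
    sl <- slotTable(timeline)
    slot <- findInterval(tms - 1e-9, sl$start)   # rating at phase end
    stressProf <- c(1.5, 3, 4.2, 2)[slot]
    effProf <- c(4.5, 3.2, 2.6, 2.8)[slot]

    sp2 <- stats::var(stressProf) * (length(stressProf) - 1) / length(stressProf)
    tgt <- correlationTarget
    se2 <- max(0.64, min(25, if (tgt > -0.99) sp2 * (1 - tgt) / (1 + tgt) + 0.05
                             else 25))
    se <- sqrt(se2)
    # The rounding/clamping to the 1-5 scale attenuates the analytic noise
    # correction, so the noise correlation is calibrated on the discrete
    # scale by simulation before drawing the session's ratings.
    discCorr <- function(rho, nRep = 400) {
      a <- rnorm(nRep * length(tms), 0, se)
      b <- rho * a + sqrt(max(0, 1 - rho^2)) * rnorm(length(a), 0, se)
      pr <- rep(stressProf, nRep)
      c1 <- pmax(1, pmin(5, round(pr + a)))
      c2 <- pmax(1, pmin(5, round(pr + b)))
      if (sd(c1) == 0 || sd(c2) == 0) return(0)
      cor(c1, c2)
    }
    rho <- if (tgt >= 1) 1 else if (discCorr(-1) >= tgt) -1 else
      stats::uniroot(function(r) discCorr(r) - tgt, c(-1, 1),
                     tol = 1e-3)$root
    e1 <- rnorm(length(tms), 0, se)
    e2 <- rho * e1 + sqrt(max(0, 1 - rho^2)) * rnorm(length(tms), 0, se)
    clamp <- function(x) as.integer(pmax(1, pmin(5, round(x))))
    new("SubjectiveRatings",
        times = tms,
        atco = clamp(stressProf + e1),
        smeStress = clamp(stressProf + e2),
        smeEfficiency = clamp(effProf + rnorm(length(tms), 0, 0.5) - 0.2 * e1))
  })
}

#' Simulate a merged feature table directly
#'
#' Draws a [StressFeatureTable-class] at the feature level (no raw signals):
#' each feature is log-normal noise around a per-subject level, multiplied by
#' the per-slot stress gain for the stress-responsive features. The noise is
#' a moving average of white innovations over `window/step` rows — exactly
#' the autocorrelation that overlapping 30-s windows impose mechanically
#' (triangular, vanishing beyond one window length), so rows one window
#' apart are independent as they are in the extracted tables. This is the
#' light-weight counterpart to running the full extraction pipeline and is
#' intended for statistical calibration studies (screening specificity,
#' permutation-null uniformity) where hundreds of sessions are needed.
#'
#' @param timeline a [ScenarioTimeline-class].
#' @param subject subject identifier stored in the labels.
#' @param effect multiplier on the log stress effect; 0 gives a null table.
#' @param window,step merge window and step, seconds.
#' @param seed integer seed.
#' @param sigma noise standard deviation on the log scale.
#' @return a [StressFeatureTable-class] with the default 58 features.
#' @export
simulateFeatureTable <- function(timeline, subject = "S1", effect = 1,
                                 window = 30, step = 0.5, seed = 1,
                                 sigma = 0.25) {
  withSeed(seed, {
    dur <- sessionDuration(timeline)
    starts <- seq(0, by = step, length.out = floor((dur - window) / step))
    labels <- timelineLabels(timeline, starts)
    chans <- featureChannels()
    bands <- c("theta", "alpha", "beta", "gamma")
    feats <- c(as.vector(outer(chans, bands, function(c, b)
      paste("psd", c, b, sep = "_"))), "lf_hf", "scl")
    nF <- length(feats); nW <- length(starts)

    stressFeat <- !grepl("_Cz_", feats)          # Cz stays stress-silent
    logGain <- log(c(1, 1.15, 1.3, 1.25)) * 2    # power-scale slot effect
    eff <- outer(ifelse(stressFeat, effect, 0), logGain[labels$slot])

    subjShift <- rnorm(nF, 0, 0.2)               # stable per-subject offsets
    L <- max(1L, round(window / step))           # rows sharing samples
    innov <- matrix(rnorm(nF * (nW + L - 1), 0, sigma * sqrt(L)),
                    nF, nW + L - 1)
    cs <- cbind(0, t(apply(innov, 1, cumsum)))
    noise <- (cs[, (L + 1):(nW + L)] - cs[, 1:nW]) / L
    X <- exp(log(10) + subjShift + eff + noise)
    rownames(X) <- feats

    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(features = X),
      colData = S4Vectors::DataFrame(
        windowStart = starts, slot = labels$slot, phase = labels$phase,
        workload = labels$workload, stress = labels$stress, subject = subject))
    S4Vectors::metadata(se)$window <- window
    new("StressFeatureTable", se)
  })
}
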