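---
title: "Multimodal stress-index methodology"
author: "stressfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal stress-index methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stressfusion)
```

## The problem

Operators of safety-critical systems — the motivating case is air traffic
control — experience acute stress whose physiological after-effects outlast
the stressful events themselves, while the operators' own ratings relax as
soon as the events are over. An objective stress measure therefore has to be
built from continuously recorded physiology rather than from self-report.
`stressfusion` implements such a measure: a fused linear discriminant over
EEG band powers, the LF/HF heart-rate-variability ratio and the tonic skin
conductance level, trained under a workload-matched cross-validation and
validated against a permutation null.

## The session model

A session lasts `T` seconds (canonically 3600) and is divided into four
equal stress slots — none, medium, high, none — each split into three
workload phases ordered LOW, MEDIUM, HIGH. Three 20-s stressful events sit
in the medium-stress slot and three in the high-stress slot, one per phase,
so stress and workload are orthogonal by design: the first and third slots
share the same workload sequence and differ mainly by the presence of
events. Subjective 1-5 ratings (operator stress, supervisor stress,
supervisor efficiency) are collected at every phase boundary.
`generateTimeline()` builds this plan; all intervals are half-open
`[start, end)`.

## Signal models in the synthetic generator

No public recordings accompany this analysis, so the package ships a
generator whose outputs carry a `GroundTruth` object recording the true
value of everything the extractors later estimate. The generator defines the
study conditions for every test in the package; its defaults were fixed once
as plausible resting-operator physiology and are documented here with their
units.

**EEG** (16 channels, 256 Hz, uV): 1/f background (SD 8 uV) plus four
sinusoidal rhythms at IAF-4, IAF, IAF+9 and IAF+20 Hz with
channel-group-dependent amplitudes (posterior alpha dominant). During the
stress slots the oscillation amplitudes of the frontal and parieto-occipital
channels are multiplied by the per-slot gain `c(1, 1.15, 1.3, 1.25)`; the
elevated final-slot gain emulates the persistence of the stress response
after the events cease. `Cz` never receives the gain and serves as a
stress-silent control feature. Eye blinks (400-ms half-sine, 150 uV on Fpz,
fixed posterior-decaying propagation) occur at 0.2/s; amplitude steps
(120 uV), ramps (15 uV/s) and single-sample jumps (30 uV) are injected at
2/min so each artifact-rejection criterion is exercised by construction.
No published effect sizes exist for this kind of protocol, so these gains
are free parameters of the simulation, not reproductions.

**ECG** (256 Hz, mV): a PQRST template train whose beat times come from
integral pulse frequency modulation of an instantaneous rate carrying a
0.1-Hz and a 0.3-Hz oscillation. The squared amplitude ratio of the two
oscillations is the true LF/HF and is set per slot to `c(1, 1.8, 3, 2.4)`
with a light log-normal per-window jitter; mean heart rate is 70 bpm and
total fractional RR modulation 0.05. IPFM was chosen because it yields an
unevenly sampled RR series with controllable spectral content — exactly the
Lomb-Scargle use case.

**Skin conductance** (100 Hz, uS): a smooth tonic curve through per-slot
levels `c(2, 2.3, 2.8, 2.6)` uS plus Poisson phasic impulses (per-slot rates
`c(4, 7, 10, 8)`/min, gamma amplitudes with mean 0.3 uS) convolved with the
biexponential impulse response `exp(-t/3.75) - exp(-t/1)`; these constants
are the conventional continuous-decomposition defaults.

**Ratings**: both stress series follow a per-slot mean profile
`c(1.5, 3, 4.2, 2)` — rising through the events and relaxing afterwards,
the underestimation the physiology is meant to expose — while efficiency
follows the mirrored declining profile `c(4.5, 3.2, 2.6, 2.8)`. The
operator-vs-supervisor correlation is steered to a target (default 0.51) by
correlating the rating noise around the shared profile; because rounding to
the 5-point scale attenuates that correction, the noise correlation is
calibrated by simulation inside the generator.

What the generator does *not* emulate: non-stationary electrode drift,
movement artifacts with realistic morphology, respiratory sinus arrhythmia
coupling, per-event physiological signatures (event kinds are carried as
string tags only), and inter-subject variability beyond random feature
offsets. Passing tests therefore demonstrate the correctness of the
pipeline's bookkeeping and its statistical behaviour under the assumed
signal structure, not field validity on human recordings.

## Feature extraction

**EEG.** Band-pass 1-40 Hz (5th-order Butterworth high- and low-pass,
forward-backward so features stay time-aligned with the timeline). Blink
intervals are detected on Fpz (0.5-6 Hz band, 50 uV threshold) and every
channel is corrected by subtracting its least-squares-scaled copy of the
baseline-detrended Fpz waveform; samples outside blink intervals are never
touched. This is a deliberately simple regression-based correction — it
shares the "correct, don't delete" contract of published blink-correction
algorithms without reproducing any of their internals. Epochs are 2 s
advanced by 0.125 s; an epoch is rejected when any channel exceeds 100 uV,
when any channel's least-squares slope exceeds 10 uV/s (each channel tested
independently — the strictest reading), or when any adjacent-sample
difference exceeds 25 uV. Per-epoch PSDs use a single full-length Hanning
taper (0.5-Hz bins at 2 s); band powers are bin means over IAF-anchored
bands theta `[IAF-6, IAF-2)`, alpha `[IAF-2, IAF+2)`, beta `[IAF+2,
IAF+16)`, gamma `[IAF+16, 40]`. The IAF is the spectral maximum of the
averaged parieto-occipital eyes-closed PSD within 7-13 Hz, with a 10-Hz
fallback (flagged) when no peak is at least 1.5x the in-window median. The
7-13 Hz window and the -6/-2/+2/+16 offsets are configurable conventions;
the feature set uses 14 channels (the montage minus Fpz, which the blink
correction consumes, and AFz).

**ECG.** Band-pass 5-20 Hz; Pan-Tompkins detection (derivative, squaring,
150-ms integration, dual adaptive thresholds with search-back at half
threshold, 200-ms refractory period, T-wave rejection by slope comparison
within 360 ms); RR intervals deviating more than 20% from an 11-interval
running median are replaced by cubic-spline interpolation — a documented
stand-in for unspecified toolbox defaults, configurable. LF (0.04-0.15 Hz)
and HF (0.15-0.4 Hz) powers integrate a Lomb-Scargle periodogram of the raw
(beat time, RR) points per 30-s window — no resampling, mean removal only —
on a 4x-oversampled grid whose fundamental resolution is 1/30 = 0.033 Hz,
using the trapezoid rule. Mean HR is computed but kept out of the default
feature set (it screens as stress-insensitive); it is available behind a
flag.

**EDA.** Downsample 100 to 25 Hz behind an anti-alias low-pass; smooth with
a 1-s Gaussian (suppressing quantisation steps); deconvolve with the
biexponential impulse response by Tikhonov-regularised frequency-domain
division. The regularisation weight is chosen by the discrepancy principle:
the largest weight on a log grid whose reconstruction stays within 2%
relative error. The driver's running low quantile (10th percentile over
+/-5 s, interpolated and smoothed) forms the tonic driver; tonic = tonic
driver convolved with the response, phasic = residual. A full non-negative
optimisation of per-subject response shapes is intentionally out of scope:
the tested contract is the tonic/phasic split, driver non-negativity and
reconstruction fidelity.

## Fusion, screening and the stress index

Features are merged every 30 s with a 0.5-s moving window: EEG band powers
averaged over the clean epochs fully inside the window, SCL over the 5-s
sub-windows inside it, LF/HF from the covering non-overlapping 30-s HRV
window. Rows are labelled at the window start (windows straddling phase
edges inherit the start's phase — a reproducible, logged convention), and
rows with any missing modality are dropped rather than imputed. A 3600-s
session yields (3600-30)/0.5 = 7140 rows of 58 features (56 PSD + LF/HF +
SCL).

Screening compares per-subject means of slot 1 vs slot 3 by an exact
Wilcoxon signed-rank test per feature (the two slots share the workload
sequence, so the contrast isolates stress). The exact distribution is
computed by convolution, which remains exact under mid-ranks.

The SWLDA enters features by minimal partial-F p-value below 0.05 and
removes features above 0.10, capped at 60 — the common stepwise convention,
stated nowhere in the source analysis and therefore a package default. The
three cross-validation folds train on the LOW, MEDIUM and HIGH workload
phases of slots 1 and 3 respectively and test on the remaining nine phases.
Per fold, z-scoring is fitted on the training rows only and SMOTE (k = 5,
Euclidean metric on the z-scored features) balances only the training rows;
the fold order (split, then normalise, then oversample) is the leakage-safe
choice and an audit log records the fitting row sets. The stress index is
the per-step mean of the discriminant over the folds in which the step was
test data. ACC uses a logistic mapping of the score calibrated by the
training class means and pooled SD; the final slot is scored but excluded
from the "none" reference because residual stress is precisely the effect
of interest there.

## The permutation null

Rows 0.5 s apart are almost identical, so shuffling labels at the row level
would fabricate an optimistic null. Instead the twelve phase labels (three
each of none, medium, high, post) are permuted across phases, the entire
pipeline — normalisation, SMOTE, stepwise fit — is re-run under each
permutation, and fold-averaged AUC/ACC are recorded; folds whose workload
level lacks a none or high phase under a permutation are skipped. The
measured run is the identity assignment of the same engine, so measured and
null values are computed by identical code paths. Permutation p-values use
the add-one convention `(1 + #{null >= measured})/(n + 1)`.

One granularity limit is worth knowing: when the classes are strongly
separable the AUC saturates at 1, and any permutation that happens to
assign its none/high labels concordantly with the injected gain ordering is
a truth-equivalent relabelling that also reaches 1. The permutation p can
therefore not fall below the fraction of such relabelings however strong
the effect. For this reason the summary comparison of measured against null
follows the paired form — per-subject measured AUC against the subject's
null mean, compared by signed-rank across the cohort — with the raw
permutation p reported alongside.

## Numerical choices and degenerate inputs

* Filters are applied forward-backward; all reported example attenuations
  refer to the squared response.
* The epoch count for duration `T` is `floor((T - 2)/0.125) + 1`; the
  merged row count is `floor((T - 30)/0.5)` (window starts `0 ... T - 30.5`),
  matching the printed 7,140 for an hour.
* A blink-free recording passes through the blink corrector bit-identically;
  a flat ECG yields an empty beat series with a warning; a constant
  conductance decomposes into pure tonic; all-zero rating differences give
  p = 1 with a warning.
* Degenerate configurations (zero duration, inverted filter edges, inverted
  impulse-response constants, `pEnter >= pRemove`, minority class smaller
  than the SMOTE neighbourhood) raise errors rather than propagating.
* When no feature passes entry, the cross-validation falls back to the
  single best feature with a warning rather than failing the fold.

## Problem sizes used in the tests

The suite exercises the canonical 3600-s session once (for the 7140 x 58
bookkeeping) and otherwise uses structurally identical 720-s sessions
(twelve 60-s phases, 20-s events) with eight synthetic subjects for the
cohort-level properties, 200 permutations for the null comparison and 24
null batches of 99 permutations for the p-value uniformity check. These
sizes were chosen as the smallest at which the checked effects are stable
across seeds.

## Known limitations

* The blink correction is a single-reference regression; it will partially
  remove any activity correlated with the Fpz waveform inside a blink
  interval.
* The EDA decomposition uses fixed impulse-response constants; real
  recordings benefit from per-subject response-shape fitting.
* AUC/ACC are averaged over folds before the pairwise comparison; the
  reverse order is also reported by `evaluateStress()` because the source
  analysis is ambiguous on this point.
* Reported discrimination figures on synthetic cohorts depend on the
  injected effect sizes, which are free parameters; they are analogues of
  the human-subject findings, not reproductions.
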