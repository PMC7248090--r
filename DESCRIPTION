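Package: stressfusion
Title: Multimodal Neurophysiological Stress Index from EEG, ECG and
    Electrodermal Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to derive an objective operator stress index from
    simultaneous electroencephalographic (EEG), electrocardiographic (ECG)
    and galvanic skin response (GSR) recordings collected during structured
    workload scenarios such as air-traffic-control simulations. The package
    covers EEG band-power extraction with individual-alpha-frequency band
    definitions and artifact rejection, Pan-Tompkins QRS detection with
    Lomb-Scargle heart-rate-variability spectra, continuous decomposition of
    skin conductance into tonic and phasic components, stress-sensitivity
    screening by exact Wilcoxon signed-rank tests, feature fusion on a
    common 30-second time base with z-score normalisation and SMOTE class
    balancing, stepwise linear discriminant (SWLDA) stress-index computation
    under workload-matched cross-validation, and evaluation of the index
    against a phase-shuffled permutation null. A synthetic-session generator
    reproduces the statistical structure the analysis assumes so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), methods
Imports:
    stats,
    utils,
    signal,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
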