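Package: wavecoh
Title: Wavelet Coherence Analysis of Paired Physiological Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-resolved Morlet wavelet coherence for paired physiological
    recordings such as mechanomyography (MMG), mechanotendography (MTG) and
    electroencephalography (EEG) of two mechanically coupled subjects.
    Provides a synthetic generator for coupled two-subject trials, the signal
    conditioning chain (notch, bandpass, decimation, drift removal, EEG region
    averaging), wavelet coherence with pointwise surrogate-data significance,
    extraction of connected significant time-frequency patches with the patch
    statistics Sum5PaD and WFreq, and a real-versus-random pairing comparison
    layer with paired t-tests, Wilcoxon signed-rank tests, repeated-measures
    ANOVA with Greenhouse-Geisser correction and the associated effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    signal,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
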