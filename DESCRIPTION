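Package: aefsim
Title: Biophysical Simulation and Analysis of Auditory Evoked Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates source-localised auditory evoked fields from a reduced
    two-layer neocortical column of multi-compartment pyramidal neurons and
    single-compartment basket cells driven by a canonical
    proximal-distal-proximal input sequence, and quantifies the resulting
    current-dipole waveforms: trial averaging, network scaling, Hamming
    smoothing, N100m amplitude/latency and slope measures, RMSE-based drive
    parameter fitting, repeated-measures ANOVA, and a synthetic multi-subject
    waveform generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
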