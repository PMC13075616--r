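Package: iednet
Title: Spectral and Network Analysis of Scalp-Negative Interictal Discharges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneous scalp and intracranial EEG
    recordings of medial temporal interictal epileptic discharges (IEDs) that
    are invisible on the scalp. Provides a synthetic multi-patient cohort
    generator with programmed ground truth, EDF input/output and standard
    preprocessing (zero-phase Butterworth filtering, downsampling, common
    average and bipolar re-referencing), spike-locked epoching with adaptive
    band-dependent Tukey windows, generalized Morse wavelet time-frequency
    maps (ERSP and inter-trial coherence) with cone of influence, band power
    spectral density, weighted phase lag index connectivity, weighted graph
    segregation and integration metrics, and group statistics
    (cluster-based sign-flip permutation tests, one-sided exact Wilcoxon
    signed-rank tests with false discovery rate correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
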