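Package: neuroclock
Title: Data-Driven Kinetic Model of the Neurospora crassa Circadian Clock
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An 18-state ordinary-differential-equation model of the
    transcription-translation feedback loop driving circadian rhythms in
    Neurospora crassa, including blue-light input through the photoreceptor
    species WCC* and VVD*. Provides a stiff-tolerant adaptive integrator with
    exact handling of light-protocol discontinuities, maximum-likelihood
    fitting of kinetic parameters to promoter-specific luciferase reporter
    time courses with multi-start Latin-hypercube initialization, rhythm
    analysis (period, phase, amplitude, damping, fold induction), in-silico
    experiments (maturation-chain scans, light-dose response, WCC
    reactivation-rate scans, entrainment balance, long dark runs, leave-out
    validation), and a certified synthetic-data generator emulating replicate
    bioluminescence tables for wild-type and delta-vvd strains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minqa,
    Rcpp
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
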