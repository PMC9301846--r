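Package: mslsh
Title: Locality-Sensitive Hashing for Signal Classification in MS1 Raw Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies centroided MS1 peak data from LC-MS and LC-IMS-MS
    experiments into signal and noise using sign-random-projection
    locality-sensitive hashing of short mass-axis windows. Windows whose
    banded hash signatures collide with any other window are self-similar
    and called signal; isolated windows are called noise. Includes an
    averagine-based isotope-pattern reference database for deisotoping and
    charge-state assignment, a labelled synthetic benchmark generator with
    Poisson/exponential noise and averagine isotopic patterns, an
    intensity-threshold baseline classifier, and ROC / precursor-matching /
    reduction-rate evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    optparse,
    jsonlite
Config/testthat/edition: 3
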