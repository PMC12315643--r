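Package: statedyn
Title: Brain-State Dynamics and Network Temporal Variability for
    Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for resting-state brain dynamics:
    maximum-likelihood Gaussian hidden Markov models on parcellated BOLD
    network time series with fractional-occupancy and switching-rate
    metrics, within- and between-network temporal variability of windowed
    functional connectivity, and covariate-adjusted partial-correlation
    association testing with false-discovery-rate control. Includes a
    synthetic cohort generator with planted state-switching and
    connectivity-variability effects for validation and power analysis.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
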