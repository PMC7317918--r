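Package: cardiocoh
Title: Wavelet Phase Coherence Analysis of Cardiorespiratory Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-frequency analysis of simultaneously recorded cardiovascular
    signals: continuous wavelet transforms on a logarithmic frequency grid
    (lognormal and Morlet wavelets), ridge extraction of instantaneous heart
    and respiration rates, wavelet phase coherence with IAAFT-surrogate
    significance thresholds, and nonparametric group comparisons across
    exposure conditions and genotype groups. Includes a synthetic cohort
    generator emulating periodic breathing under hypoxia so that the full
    pipeline can be exercised and calibrated without access to recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
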