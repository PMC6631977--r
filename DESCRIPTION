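Package: nirCPANN
Title: Counter-Propagation Neural Network Classification of Near-Infrared
    Tissue Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification of near-infrared (NIR) transflectance spectra of
    tissue sections with a counter-propagation artificial neural network
    (CP-ANN), as used to discriminate BRAF V600E mutant from wild-type
    colorectal-cancer tissue. Provides spectral containers built on
    SummarizedExperiment, the standard chemometric preprocessing operators
    (mean centering, multiplicative scatter correction, standard normal
    variate, derivatives, Savitzky-Golay and Norris smoothing) with strict
    fit-on-calibration semantics, principal-component feature reduction with
    a cumulative-variance selection rule, a from-scratch supervised Kohonen
    (counter-propagation) classifier with grouped cross-validation, per-sample
    diagnostics with replicate voting, and a synthetic two-class spectra
    generator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
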