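Package: dropqs
Title: Droplet Microfluidics Models of Density-Dependent Macrophage Cytokine Secretion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for single-cell droplet-microfluidics
    studies of macrophage IL-10 and TNF-alpha secretion. Implements Poisson
    cell-encapsulation statistics with goodness-of-fit checks, a multi-cell
    droplet IL-10 positivity model (the published summation formula, an
    exact-expectation variant, and a stochastic droplet simulator) with
    producer-fraction estimation and confidence bands, titration-curve-based
    absolute cytokine quantification (log-log interpolation or four-parameter
    logistic), density and time-course secretion-rate analysis with clearance
    flagging, and synthetic-data generators that emulate every pipeline input,
    tied together by a validated CSV pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
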