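Package: nirda
Title: Domain Adaptation for Near-Infrared Spectral Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transferring near-infrared (NIR) spectral classifiers
    from stationary (source domain) to moving (target domain) samples, as
    needed for in-line monitoring of agri-food powders on conveyor systems.
    Implements domain-adversarial neural networks (DANN), semisupervised
    generative adversarial networks (SGAN), their combination, and a plain
    transfer-learning baseline, all sharing one fully connected feature
    extractor trained with sequential adversarial loss schedules and a
    reciprocal ("negative inverse") adversarial transform. Includes
    deep-ensemble majority-vote confidence scoring, permutation-based
    wavelength importance with contiguous-range extraction, a synthetic
    spectra generator with Gaussian absorption bands and speed-dependent
    intensity shifts, domain-split construction, an experiment-grid runner,
    and a YAML-configured pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
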