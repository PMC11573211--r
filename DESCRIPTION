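Package: somaqc
Title: Quality Control and Standardisation for Aptamer Proteomics of Synovial Fluid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an end-to-end quality-control and standardisation
    pipeline for aptamer-based (SomaScan-style) proteomics of synovial fluid:
    ADAT-style input/output, hybridisation-control normalisation, plate
    scaling and calibration, repeatability metrics (percent CV and
    non-technical R-squared), an intracellular protein score (IPS) estimated
    from paired spun/unspun samples with linear-model adjustment, bimodal
    batch detection by a Gaussian mixture on PC2 with parametric
    empirical-Bayes ComBat correction, PCA diagnostics, the full SOMAmer and
    sample filter battery with blank-based limits of detection, and a
    multi-plate synthetic data generator with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
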