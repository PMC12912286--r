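Package: scregress
Title: Short-Separation Channel Regression Strategies for fNIRS GLM Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ecological block-design functional near-infrared
    spectroscopy (fNIRS) sessions with known ground-truth neural amplitudes
    and realistic systemic physiology (Mayer waves, cardiac and respiratory
    oscillations, slow drift, motion artifacts), preprocesses them (optical
    density conversion, temporal derivative distribution repair, band-pass
    filtering, modified Beer-Lambert law), and compares ten general linear
    model variants that differ in how short-separation channel signals are
    used as nuisance regressors (none, nearest, most-correlated, mean,
    pooled raw, pooled principal components; under limited or full
    short-channel availability). Pipelines are scored with directional
    Jeffreys-Zellner-Siow Bayes-factor t-tests via two validation metrics:
    channel-level emergence of modality-appropriate activation and
    between-condition contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
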