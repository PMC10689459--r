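Package: doseresp
Title: Significance Analysis of High-Throughput Dose-Response Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits four-parameter log-logistic models to high-throughput
    dose-response curves and assigns each curve a calibrated p-value from a
    recalibrated F-statistic with effective degrees of freedom. Significance
    and effect size are combined into a relevance score with hyperbolic
    decision boundaries derived from an s0 fudge factor, curves are
    classified as up-, down-, not regulated or unclear, and false discovery
    rates are estimated by scoring simulated decoy curves built from the
    dataset's own variance distribution. Includes a TOML-configured pipeline
    for TSV/CSV dose-response tables, preprocessing (control normalization,
    median centering, quantile imputation), null-hypothesis simulation for
    calibration checks, and synthetic fixture generators with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
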