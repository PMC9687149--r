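Package: alternanspop
Title: Population Modelling of APD Alternans in Human Ventricular Myocytes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a human ventricular epicardial myocyte model under a
    descending cycle-length pacing protocol and quantifies beat-to-beat
    action potential duration (APD) alternans. Provides APD90 extraction,
    alternans magnitude and normalized alternans magnitude biomarkers,
    alternans onset cycle length detection, a three-level factorial sweep
    over ten maximal ion channel conductances, and dimensionally stacked
    population maps whose axis ordering is optimized to expose the most
    influential conductances. Includes seed-deterministic synthetic
    generators (analytic action-potential trains and planted scalar fields)
    so every pipeline stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
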