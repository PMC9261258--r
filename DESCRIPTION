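Package: stepcal
Title: Stepwise Calibration of Multiscale Mechanistic Models with CMA-ES
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calibrating mechanistic models against heterogeneous
    biological constraints. Binary knowledge rules and continuous data-fit
    rules are scored into [0,1] and combined into a single weighted objective,
    which is maximized with a from-scratch Covariance Matrix Adaptation
    Evolution Strategy (CMA-ES). Calibration proceeds in ordered steps that
    freeze solved parameters, transfer rates across biological scales by
    allometric power laws, and re-verify earlier constraints. Ships a
    rim-structured tumor spheroid/xenograft growth model and a synthetic-data
    generator emulating in vitro spheroid radius and mouse-xenograft volume
    time courses, used in a worked stepwise lung-adenocarcinoma calibration
    example with genotype-dependent gefitinib response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
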