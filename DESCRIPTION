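Package: missdag
Title: Canonical Missingness DAGs, Recoverability and Estimation for
    Point-Exposure Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reasoning about and handling missing data in
    point-exposure epidemiologic studies with missingness directed acyclic
    graphs (m-DAGs). Encodes the ten canonical m-DAGs spanning the sixteen
    classes of missingness mechanisms for a study with incomplete exposure,
    outcome and confounders; reports, for each canonical graph, whether the
    joint, marginal and conditional target distributions (and the exposure
    mean, outcome mean and regression-adjusted association) are recoverable
    from the observed-data distribution; evaluates the corresponding
    identification formulas by plug-in standardization and sequential
    inverse-probability weighting; and compares available-case analysis
    with multiple imputation by chained equations in a replicated
    simulation study, including d-separation utilities, a calibrated
    synthetic-data generator and Rubin's-rules pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
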