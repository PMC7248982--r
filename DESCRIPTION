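Package: milkwdi
Title: Pharmacokinetics and Milk Withdrawal Interval Estimation for
    Veterinary Residue Depletion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for noncompartmental pharmacokinetic analysis of parent
    drug and metabolite plasma profiles, four-parameter logistic immunoassay
    calibration with assay-limit derivation, Monte Carlo augmentation of
    sparse milk residue data, and regression-based tolerance-limit estimation
    of milk withdrawal intervals under the EMA safe-concentration-from-linear-
    regression (95th percentile, 95% confidence) and FDA (99th percentile,
    95% confidence) conventions. Includes a crossover-study simulator that
    generates plasma and milk concentration-time data with known ground truth
    so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
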