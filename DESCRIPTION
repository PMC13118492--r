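Package: residuerisk
Title: Pesticide Residue Monitoring Statistics and Dietary Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for multi-residue pesticide monitoring surveys
    of food commodities. Provides occurrence and maximum-residue-level (MRL)
    exceedance summaries with chi-square homogeneity tests across regions,
    the Index of Quality for Residues (IqR) with four-category sample
    classification, a matrix-based risk ranking score for prioritising
    compounds, deterministic chronic and acute dietary exposure (NEDI, IESTI
    Case 2a, hazard quotients and hazard indices) under lower-, middle- and
    upper-bound treatment of left-censored concentrations, probabilistic risk
    characterisation by Monte Carlo simulation with contribution-to-variance
    sensitivity analysis, SANTE-style method-validation metrics, and a
    seedable synthetic-data generator that emulates the occurrence structure
    of large monitoring surveys (detection frequencies, truncated log-normal
    concentrations, multi-residue co-occurrence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
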