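Package: gadnca
Title: Noncompartmental Pharmacokinetics of Gadoxetate as a Liver-Function Readout
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noncompartmental pharmacokinetic (NCA) analysis of gadoxetate
    (Gd-EOB-DTPA) serum concentration-time profiles, built around a rat
    partial-hepatectomy study design in which vascular clearance of the
    contrast agent serves as a quantitative liver-function test. Provides
    linear-up/log-down trapezoidal AUC and AUMC integration, terminal-phase
    rate-constant regression with automatic window selection, clearance and
    volume-of-distribution estimation, liver lobe-weight and regeneration
    arithmetic, a three-group statistical comparison layer (one-way ANOVA,
    Bonferroni-corrected pairwise Student t tests, Spearman trend), and a
    two-compartment synthetic cohort generator so the full pipeline is
    testable without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
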