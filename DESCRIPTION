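Package: copstab
Title: Postural Sway and Local Dynamic Stability Analysis for Inhalation-Challenge Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying quiet-standing postural control from
    centre-of-pressure (COP) recordings: sway path lengths, local dynamic
    stability via the Rosenstein largest Lyapunov exponent with average
    mutual information delay selection and false nearest neighbors
    dimension selection, respiration-rate extraction from band-passed
    breathing traces, and the repeated-measures statistical stage
    (two-way within-subject ANOVA with Greenhouse-Geisser correction,
    partial eta squared, Bonferroni pairwise comparisons, and change-score
    correlations). Includes a synthetic-cohort generator that emulates a
    balanced inhalation-challenge study design (Air vs CO2-enriched air)
    with injectable condition effects, plus deterministic chaotic fixtures
    and an independent tangent-space Lyapunov oracle for validating the
    nonlinear stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
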