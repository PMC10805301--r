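Package: edacr
Title: Emergency Department Avoidability Classification and Agreement-Study Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Emergency Department Avoidability Classification
    (EDAC), a deterministic decision table that retrospectively labels
    emergency department visits as avoidable, potentially avoidable or not
    avoidable from five administrative variables, together with the full
    analytic pipeline of a clustered, blinded dual-rater agreement study
    validating it against physician judgement: stratified cluster sampling and
    blinded rater assignment, pooled-marginal Cohen's kappa with asymptotic
    and bootstrap intervals, tie-corrected Spearman correlation, cumulative-
    logit (proportional odds) regression with dichotomized odds ratios and an
    ordinal concordance index, precision analyses under three regroupings of
    the middle class, a simulation-based power calculator for kappa criteria,
    and a synthetic cohort/judgement generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    MASS,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
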