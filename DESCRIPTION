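Package: ddcohort
Title: Life-Span Delay Discounting: Hyperbolic Rate Estimation, Time
    Perception, and Robust Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intertemporal-choice cohorts across the adult
    life span. Estimates per-subject hyperbolic discount rates from binary
    smaller-sooner/larger-later choices by maximum likelihood under a logistic
    (softmax) choice rule, with convergence screening and exclusion; fits the
    anticipatory time-perception power law T = alpha * t^beta per subject with a
    bounded Huber-robust loss and two-stage outlier exclusion; provides
    from-scratch robust statistics (tie-corrected Kendall tau-b, Huber
    M-estimate of location, Huber M-regression, high-breakdown MM-regression,
    classical ANCOVA F) and percentile-bootstrap single-mediator models; and
    orchestrates the full cohort analysis (age-group assignment, age-bias
    scores, per-group correlation tables, interaction models, sex tests,
    mediation) into a reproducible report. A seeded synthetic-cohort generator
    emulates the statistical structure such studies assume, so the whole
    pipeline is testable without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
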