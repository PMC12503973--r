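Package: targetMR
Title: Proteome-Wide Mendelian Randomization for Drug-Target Triangulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Two-sample summary-data Mendelian randomization (MR) pipeline
    for triangulating plasma-protein drug targets against a disease
    outcome. Implements cis-pQTL instrument selection (cis window,
    genome-wide significance, greedy LD clumping, variance explained and
    F-statistic weak-instrument filtering), a suite of causal estimators
    (Wald ratio, fixed and multiplicative random-effects IVW, MR-Egger,
    weighted median, mode-based estimators, MR-PRESSO), a
    diagnostics-driven method-adjudication rule with Bonferroni
    discovery/replication logic and fixed-effect meta-analysis, Bayesian
    colocalization via approximate Bayes factors, and SMR with the HEIDI
    linkage test. A summary-statistics simulator with known ground truth
    (shared-variant, linkage, pleiotropy, outlier and weak-instrument
    architectures under autoregressive LD) makes every stage testable
    without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
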