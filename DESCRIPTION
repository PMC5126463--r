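Package: traumaDyNA
Title: Base-Deficit-Stratified Analysis of Trauma-Induced Systemic Inflammation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to stratify blunt trauma cohorts at an admission base
    deficit cutoff and characterise the divergent systemic inflammatory
    response of the two strata. Implements cohort exclusion rules and
    clinical contingency statistics (relative risk with Katz log
    confidence intervals, chi-square, Fisher exact, Mann-Whitney U),
    time-binned cytokine trajectory analysis (two-way group-by-time
    ANOVA with Type III sums of squares, trapezoidal AUC and fold-change
    ranking), and Dynamic Network Analysis (DyNA): per-group correlation
    networks over adjacent time windows with a thresholded edge rule and
    an edge-times-node density metric. Includes a seed-reproducible
    synthetic cohort generator with plantable correlation blocks so that
    network recovery is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    igraph,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
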