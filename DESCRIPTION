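Package: cdtriad
Title: Three-Marker Panel Diagnostics for Endoscopic Remission in Crohn's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating multi-marker diagnostic rules for
    endoscopic remission in Crohn's disease from three non-invasive inflammation
    markers: serum leucine-rich alpha-2 glycoprotein (LRG), serum C-reactive
    protein (CRP) and fecal calprotectin (Fcal). Implements Youden-index cutoff
    selection on empirical ROC curves, k-of-n majority and all-negative
    combination rules, a sequential two-step triage rule that measures fecal
    calprotectin only when the serum markers disagree, DeLong comparison of
    correlated AUCs, exact and Wald binomial confidence intervals, stratified
    k-fold cross-validation with per-fold cutoff refitting, Kaplan-Meier /
    log-rank / Cox analysis of rule-stratified prognosis, a consistency audit
    that reconstructs confusion matrices from published accuracy tables, and a
    synthetic cohort generator with stratum-conditional log-normal marker
    distributions coupled by a Gaussian copula.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
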