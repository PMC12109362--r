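Package: branchflow
Title: Branch Stent-Graft Hemodynamics After Fenestrated/Branched EVAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational pipeline for studying how the tilt
    angle, entry depth and diameter of a renal branch stent control branch
    blood flow after fenestrated or branched endovascular aneurysm repair
    (F/B EVAR). Builds parametric two-dimensional models of an aortic
    conduit with a protruding branch stent (including a beveled-tip
    variant), solves steady incompressible Newtonian flow with a
    staggered-grid SIMPLE finite-volume scheme, post-processes branch mass
    flow, reflux/outflow classification, wall shear stress and
    recirculation area, drives parameter sweeps and beveled-tip
    comparisons, and runs the clinical statistics stage (median flow split,
    exact small-sample Mann-Whitney U, Kolmogorov-Smirnov normality
    gating, Cohen's d) on per-artery case records, with a synthetic cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    jsonlite,
    withr
Config/testthat/edition: 3
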