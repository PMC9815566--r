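Package: braotrial
Title: Retinal Ganglion Cell Layer Decay Modelling and Trial Planning for
    Branch Retinal Artery Occlusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the time course of ganglion cell layer (GCL)
    thinning after branch retinal artery occlusion (BRAO) from quadrant-resolved
    optical coherence tomography (OCT) layer-thickness tables, and for planning
    neuroprotection trials from the fitted course. Computes percent thickness
    change of the affected eye against a fellow-eye or normative reference,
    fits a single-phase exponential decay curve by nonlinear least squares,
    projects treated-arm means under hypothetical drug efficacies, converts
    them to Cohen's d effect sizes, and derives minimum per-group sample sizes
    for a two-sided two-sample t-test via the noncentral t distribution. A
    synthetic-cohort generator with a known ground-truth ledger supports
    parameter-recovery validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
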