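Package: slnrisk
Title: Sentinel Lymph Node Positivity Modelling for Clinically
    Node-Negative Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits and evaluates a multiplicative exponential risk model for
    the probability that the sentinel axillary lymph node of a clinically
    node-negative breast cancer patient is metastatic, Ln = 1 - exp(-Qn *
    prod(gi) * D^Z), where D is the primary tumour diameter in mm, gi are
    per-level multipliers for discrete prognostic factors (age class,
    histologic type, ER, PR, grade, optionally Ki67 and HER2) and Qn is a
    population interpolation parameter.  Calibration is the two-phase
    moment-matching procedure used by lymph-node involvement calculators:
    Qn is solved on the whole training cohort with all gi = 1, then each
    level's gi is solved on its stratum with Qn held fixed.  The package
    also provides the accompanying evaluation protocol (rank-based AUC,
    Youden-index threshold selection, hold-out splitting, repeated
    stratified k-fold cross-validation with median/quartile summaries,
    clinical subgroup stratification including St. Gallen molecular
    subtypes) and a synthetic cohort generator that emulates the marginal
    structure of a published institutional cohort so the whole pipeline is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
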