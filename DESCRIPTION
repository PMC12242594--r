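Package: lumpsplit
Title: Lumping and Splitting of Syndrome Subgroups from Facial
    Phenotype Descriptors and Methylation Episignatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical delineation of candidate syndrome subgroups
    ("lumping versus splitting"). Compares cohorts of patients embedded
    as ensembles of facial phenotype descriptors using mean pairwise
    cosine distance, calibrates a split threshold by ROC/Youden analysis
    against resampled same- and different-syndrome control
    distributions with syndrome-based cross-validation, and decides
    lump versus split by subgroup resampling with a positive predictive
    value estimate. Companion modules provide exact two-tailed Fisher
    testing of clinical 2x2 phenotype tables with Bonferroni
    correction, and DNA-methylation episignature discovery and
    classification (moderated-t differential methylation with FDR and
    delta-beta filtering, linear support-vector scoring on 0-1 scale).
    Synthetic generators for descriptor collections on the unit
    hypersphere and for beta-value matrices with planted signatures
    make every statistical operation testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
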