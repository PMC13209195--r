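Package: qsarphore
Title: Pharmacophore Hypotheses, Grid-Occupancy 3D-QSAR and Shape Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based discovery pipeline for enzyme inhibitors built around
    common-pharmacophore hypothesis generation with survival scoring,
    hypothesis-aligned binary grid-occupancy 3D-QSAR fitted by partial least
    squares with a full external-validation suite (q2, r0^2, k, rm^2, LOO
    stability, F statistics), Gaussian shape plus pharmacophore-feature
    Tanimoto screening of conformer ensembles, multi-score fusion with a
    top-fraction cutoff, and K-means triage of surviving candidates on
    structural fingerprints. Ships a synthetic-data generator that plants a
    known pharmacophore template and a linear structure-activity signal so
    every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
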