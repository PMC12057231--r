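Package: ProteoStage
Title: Staging Analysis of CSF Proteomes Along the Alzheimer's Disease Continuum
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tandem-mass-tag (TMT) cerebrospinal-fluid proteome
    staging studies: median-ratio normalization of reporter intensities,
    robust (biweight midcorrelation) signed weighted co-expression networks
    with topological overlap, dynamic tree cutting and Eigenprotein/kME
    module summaries, hierarchical Braak staging from regional tau PET,
    amyloid and tau positivity calls from PET, CSF and cortical biopsy data,
    module-biomarker association with empirical-Bayes moderated linear
    models and Tukey HSD contrasts, cross-cohort Eigenprotein projection,
    loess stage trajectories, and elastic-net staging panels with ROC
    evaluation. Includes a synthetic multi-cohort generator with planted
    module trajectories for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
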