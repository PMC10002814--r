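Package: csfstrat
Title: CSF Biomarker Panels and Stratification of Asymptomatic Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deriving cerebrospinal-fluid (CSF) biomarker cutoffs and
    peptide panels that separate biomarker-negative controls from Alzheimer's
    disease (AD), and for stratifying cognitively normal but biomarker-positive
    (asymptomatic AD) individuals into AD-like and Control-like subgroups.
    Implements two-component Gaussian-mixture cutoff derivation for analyte
    ratios, dual-classifier recursive feature elimination with a random-panel
    permutation null, t-SNE embedding with k-nearest-neighbour pseudo-labelling
    and seed-stability probabilities, joint-mutual-information selection of a
    compact sub-grouping panel, and the supporting cohort statistics (median
    regression with bootstrap inference, Benjamini-Hochberg FDR, Kendall-tau
    ranking, Youden-index ROC cutoffs, matched-group tests). A synthetic-cohort
    generator with known ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    quantreg,
    Rtsne,
    e1071,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
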