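Package: radiocascade
Title: Cascade Radiomics Classifier for Ground-Glass Nodules on Chest CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Texture radiomics for distinguishing solitary pulmonary
    capillary haemangioma (SPCH) from lepidic-predominant adenocarcinoma
    (LPA) on chest CT. Computes 26 lesion features (5 histogram, 21
    grey-level co-occurrence matrix features over horizontally adjacent
    voxel pairs), fits a two-level divide-and-conquer cascade classifier
    (a PCA-gated support vector machine root constrained to 100%
    sensitivity for the minority class, followed by a two-feature leaf
    node) alongside a single-stage baseline, and evaluates both by
    leave-one-out cross-validation with ROC analysis and the
    Hanley-McNeil test for correlated areas under the curve. Includes
    Levene-gated two-sample t-test reporting for per-feature group
    comparisons and a seeded synthetic nodule-cohort generator for
    end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    pROC,
    car,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
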