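Package: tcmforest
Title: Nine-Constitution Discrimination from Untargeted Serum Metabolomics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating the nine traditional Chinese medicine
    (TCM) constitution types (Pinghe plus eight biased types) from untargeted
    LC-MS serum feature tables. Implements constitution questionnaire scale
    scoring and determination rules, QC-based instrument stability checks
    (pairwise Pearson correlation of pooled QC injections) and coefficient-of-
    variation feature filtering, one-vs-reference differential m/z screening
    with common/unique signature-set decomposition, per-class mean imputation,
    a from-scratch random forest (bootstrap bagging over CART trees split on
    Gini impurity, majority voting), and stratified 10-fold cross-validation
    with one-vs-rest per-class accuracy reporting. A seeded synthetic cohort
    generator emulating the study design (9 classes x 49 subjects, planted
    unique and shared differential features, QC replicates with controlled
    CV, missing intensities) makes every stage testable without real serum
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
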