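Package: dcmerp
Title: Biophysical Biomarkers from Event-Related Potentials via Neural-Mass Model Inversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Jansen-Rit neural-mass network models to two-condition
    event-related potentials (ERPs) by variational free-energy (Laplace)
    inversion, compares connectivity-modulation model variants with
    fixed-effects Bayesian model selection, and evaluates the resulting
    biophysical parameter estimates as classification and subtyping features
    against conventional ERP peak amplitude/latency features. Ships a
    synthetic-cohort generator with known ground truth (patient/control
    classes, patient subtypes, channel noise) so the whole pipeline -- SMOTE
    class balancing, cross-validated SVM/random-forest/gradient-boosted-tree
    classification scored by MCC and F1, Shapley-value feature attribution,
    and t-SNE + k-means silhouette subtype clustering -- is testable end to
    end without any recorded EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    e1071,
    randomForest,
    xgboost,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
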