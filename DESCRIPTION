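Package: lipidcrit
Title: Plasma Lipidomics of Critical Illness: Preprocessing, Lipid
    Reprogramming Score, and Mixed-Data Causal Discovery
Version: 0.1.0
Authors@R:
    person("PAMPer", "Reanalysis", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing longitudinal plasma lipid panels in
    critical illness. Implements lipid-nomenclature parsing, missingness
    filtering, minimum imputation, class/fatty-acid summaries, z-score
    normalisation and PCA/UMAP embedding; covariate-adjusted logistic and
    Wilcoxon differential screens with Benjamini-Hochberg control;
    construction and application of a composite Lipid Reprogramming Score
    (mean z-score of a phosphatidylethanolamine panel with tertile
    categories); constraint-based causal discovery on mixed data with
    nested leave-one-out cross-validated alpha selection and
    Markov-blanket prediction; correlation networks, Kaplan-Meier ICU
    recovery analysis and prognostic model comparison; plus synthetic
    trauma/COVID-like cohort generators with planted ground truth so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    quadprog,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
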