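Package: gbfs
Title: Gradient-Boosted Feature Selection and Substructure Embeddings for
    Molecular Property Prediction from SMILES
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts molecular properties (regression and binary
    classification) from SMILES strings alone. Builds a high-dimensional
    descriptor matrix (circular Morgan counts, path and MACCS fingerprints,
    atom-pair counts, physicochemical and element-property descriptors),
    ranks features by gradient-boosted loss-reduction gain and by statistical
    association (regression F-statistic, k-nearest-neighbour mutual
    information), engineers pairwise derived features, reduces
    multicollinearity by a correlation filter and Spearman/Ward hierarchical
    clustering, refines the subset by permutation importance and
    cross-validated recursive feature elimination, and fits a final
    gradient-boosted model tuned by a coarse grid search followed by
    Gaussian-process Bayesian optimization. Optionally concatenates
    skip-gram substructure embeddings (molecule-to-vector) at the
    optimization stage. Includes scaffold-aware data splitting
    (Bemis-Murcko), evaluation metrics, and a synthetic-molecule fixture
    generator with planted structure-property relationships.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    xgboost,
    data.table,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr,
    pROC,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
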