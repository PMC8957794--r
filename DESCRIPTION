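Package: swarmFS
Title: Ensemble Swarm-Intelligence Feature Selection for High-Dimensional Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for high-dimensional omics matrices
    (transcriptome expression, DNA-methylation beta values) driven by binary
    swarm-intelligence metaheuristics. Provides the slime mould algorithm (SMA),
    pathfinder algorithm (PFA), Henry gas solubility optimization (HGSO) and
    particle swarm optimization (PSO) over a shared population framework, a
    cross-validated k-nearest-neighbour fitness that trades classification
    error against subset size, multi-classifier evaluation (SVM, KNN, linear
    discriminant analysis, bagged trees, naive Bayes), ensemble combination of
    selected subsets by set intersection and union, feature-selection-rate
    tables, and nonparametric method comparison (Wilcoxon signed-rank,
    Friedman). Includes a synthetic-data generator with planted informative
    features for benchmarking selection methods without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
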