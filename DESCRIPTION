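Package: netcouple
Title: Multimodal Connectome Construction, Network-Based Statistics and
    Structure-Function Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds per-subject functional connectomes (Pearson correlation
    with false-discovery-rate edge retention) and grey-matter structural
    connectomes (Jensen-Shannon distance-based similarity between regional
    value distributions), localizes group differences with the network-based
    statistic (permutation family-wise error control over suprathreshold
    graph components), quantifies structure-function coupling at whole-brain,
    global-network, regional-node, within-network and between-network scales,
    screens coupling differences with permutation tests, and classifies
    groups with a linear support vector machine under leave-one-out
    cross-validation.  Includes a synthetic cohort generator with plantable
    connectivity and coupling effects so every stage can be validated against
    ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
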