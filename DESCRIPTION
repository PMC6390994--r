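Package: jointNMF
Title: Sparse Multilayer Non-Negative Matrix Factorization for Patterns of
    Joint Involvement in Childhood Arthritis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers hierarchical patterns of joint involvement from
    patient-by-joint binary matrices recorded on a standard homunculus of
    assessable joints. Implements joint co-involvement and same-side skew
    statistics, sparse non-negative matrix factorization fitted by
    multiplicative updates, bi-cross-validation over rank and regularization
    grids, a two-layer (multilayer) factor composition with key-joint
    extraction and mixed-membership patient grouping, a degree-of-localization
    metric with category thresholds, projection of external cohorts through a
    frozen model, longitudinal group-transition permutation tests, and
    time-to-inactive-disease survival analyses. A synthetic-cohort generator
    with planted hierarchical structure supports end-to-end testing without
    access to any registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    pracma,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
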