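Package: morphdx
Title: Multi-Diagnostic Classification of Dementia from Structural Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reusable, tested pipeline for multi-diagnostic (healthy control /
    mild cognitive impairment / Alzheimer's disease) classification from
    FreeSurfer-style morphometric feature tables. Derives subject-level
    graph-theory features from regional volume similarity graphs, trains one
    voting ensemble per binary diagnostic task using an evolutionary search
    over feature selection and classifier hyperparameters with Matthews
    correlation coefficient fitness, stacks the binary ensembles into a
    multiclass decision with a linear one-vs-one combiner, builds age-matched,
    sex-balanced, transition-aware test sets, and evaluates classifiers with
    bootstrap confidence intervals, prevalence-adjusted predictive values, and
    a clinical-applicability grade. Ships a synthetic cohort generator that
    emulates the statistical structure of multi-site, multi-protocol
    morphometry studies so the whole pipeline is testable without access to
    controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    glmnet,
    igraph,
    MASS,
    ranger,
    rpart,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
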