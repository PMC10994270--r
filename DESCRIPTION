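Package: morphoscreen
Title: Morphological Profiling Screen Analysis with Phenotypic Reversion Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Cell Painting phenotypic drug screens that
    compare gene-edited mutant cells against isogenic wild-type controls.
    Simulates 384-well screens with known ground truth, aggregates and
    normalises image-level morphological feature tables, removes degenerate
    and redundant variables, filters features by group ANOVA with
    Benjamini-Hochberg correction, reduces profiles by correlation-matrix PCA
    with oblimin factor rotation and ten Berge correlation-preserving factor
    scores, quantifies mutant/wild-type separation with Bray-Curtis and
    Euclidean permutation tests, trains control-anchored neural-network
    (plus random-forest and SVM) classifiers to score each compound-treated
    well's similarity to wild-type, calls replicated hits with salt-form
    collapsing and mechanism grouping, and performs hypergeometric gene-set
    enrichment against an expressed-gene background.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    nnet,
    randomForest,
    e1071,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    fgsea,
    withr
Config/testthat/edition: 3
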