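Package: fusemap
Title: Subject-Similarity Reference Spaces from Multimodal Brain Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds low-dimensional subject-similarity reference spaces from
    multimodal regional brain features by similarity network fusion (SNF) and
    diffusion map embedding, learns a transferable mapping from raw features
    to the first embedding score with an instance-weighted reverse-boosting
    regressor (TrAdaBoostR2 with elastic-net base learners), harmonizes
    multi-site feature tables with parametric empirical-Bayes batch
    correction, scores pubertal development and psychopathology proxies, and
    fits sex-stratified linear models of embedding (change) scores on those
    phenotypes. A synthetic-cohort generator with planted latent maturation
    structure makes every stage testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
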