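Package: neodl
Title: Neoantigen Intrinsic-Feature Survival Stratification for IDH Wild-Type Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prognostic stratification of IDH wild-type glioblastoma cohorts from the
    intrinsic sequence features of predicted neoantigens. Implements neoantigen calling
    from mutant/wild-type 9-mer peptide pairs by the 500 nM binding-affinity rule,
    position-, dipeptide-, tripeptide- and whole-sequence-level featurization over ten
    published amino-acid descriptor families, univariate Cox proportional-hazards
    screening of prognostic features, hierarchical k-means survival labelling, a
    two-layer LSTM stratifier (neoDL) trained on the derived labels, repeated
    stratified split validation and reliability resampling, baseline stratifiers
    (missense load, neoantigen count, differential agretopicity index), and a
    synthetic-cohort generator for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    pROC,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
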