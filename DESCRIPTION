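Package: finetwas
Title: Fine-Mapping- and Tissue-Sharing-Informed Transcriptome Prediction and Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds four families of genetically-regulated expression
    prediction models (elastic net, fine-mapping-weighted elastic net,
    cross-tissue group-lasso, and multivariate-adaptive-shrinkage models),
    runs summary-statistics transcriptome-wide association (gene-level
    z-scores from GWAS summary statistics, LD and model weights) with GWAS
    harmonization and best-linear-unbiased-prediction imputation of missing
    statistics, and benchmarks causal-gene identification against
    silver-standard gene-trait pairs with ROC/PR curves and bootstrap
    standard errors. Includes a synthetic-data generator for LD-structured
    genotypes, multi-tissue expression with sparse shared cis-eQTLs, and
    null or causal GWAS z-scores, plus a desk-scale Bayesian fine-mapping
    routine producing posterior inclusion probabilities and LD clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    vcfR
Config/testthat/edition: 3
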