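Package: dilisnp
Title: SNP-SNP Interaction Detection for Chronic Drug-Induced Liver Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects SNP-SNP interactions (epistasis) associated with a binary
    phenotype such as chronic versus acute drug-induced liver injury (DILI).
    Provides three interaction detectors: a from-scratch multifactor
    dimensionality reduction (MDR) engine with cross-validated model selection,
    a multivariate adaptive regression splines (MARS) engine specialised for
    categorical genotype predictors with GCV-based backward pruning, and a
    Random-Forest importance ranking followed by a logistic-regression
    interaction scan. An association layer computes odds ratios, confidence
    intervals (Wald, profile-likelihood and exact-conditional) and Fisher exact
    tests over multilocus genotype groupings; a pipeline keeps only
    interactions whose combined-genotype odds ratio beats every constituent
    SNP's marginal odds ratio, pools the surviving SNPs and fits a CART risk
    tree evaluated by stratified cross-validation. Includes genotype I/O
    (delimited text and PLINK .raw) and synthetic-data generators that emulate
    a two-locus no-marginal-effect penetrance simulation and a case-control
    cohort with exactly prescribed 2x2 contingency margins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
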