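Package: cismeth
Title: Cis-Genetic Prediction Models for DNA Methylation and
    Summary-Statistic Methylome-Wide Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds per-CpG elastic-net models that predict whole-blood DNA
    methylation from cis-SNP dosages, evaluates and selects robust models,
    and tests genetically estimated methylation for trait association either
    with individual-level genotypes or from GWAS summary statistics alone,
    using a reference-panel SNP covariance with diagonal shrinkage. Includes
    quality-control filters for SNPs and CpG probes, methylation beta/M
    transforms and covariate residualization, a linkage-disequilibrium-aware
    synthetic data generator, type-I error and power simulation studies,
    CpG-expression integration, and permutation enrichment testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
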