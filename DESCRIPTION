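Package: tensoromics
Title: Gene-Centric Multi-Omics Integration by Non-Negative Tensor Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates matched gene-expression, promoter-methylation and
    miRNA-expression matrices into a gene x sample x omics tensor, decomposes
    it by non-negative PARAFAC (CP) alternating least squares, selects
    phenotype-specific latent features by one-vs-rest L1 regression on the
    patient component, maps genes and omics layers to features by argmax, and
    scores selected features with stratified cross-validated multi-class
    classification. Includes consensus-dispersion NMF rank estimation, a
    synthetic cohort generator with planted CP structure for end-to-end
    validation, and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    knitr
Config/testthat/edition: 3
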