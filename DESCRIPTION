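Package: hegp
Title: Homomorphic Encryption of Genotypes and Phenotypes for Shared
    Quantitative Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encrypts standardized genotype dosages, phenotypes and
    covariates by multiplication with random orthogonal matrices sampled
    from the Stiefel manifold, so that linkage disequilibrium, mixed-model
    likelihoods, variance components, heritability and genome-wide
    association statistics are preserved exactly while individual-level
    data are obscured. Supports federated mega-analysis of independently
    encrypted cohorts, dual encryption for cross-cohort relatedness
    screening, quantile-normalization and rounding hardening of
    ciphertexts, the mixed-model (whitening) transformation as an
    alternative encryptor, and an audit toolkit implementing brute-force,
    Hardy-Weinberg mixture and private-variant attacks for security
    evaluation. Includes a synthetic-cohort simulator and a command-line
    interface.
License: AGPL (>= 3)
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    data.table,
    tibble,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
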