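Package: hcpart
Title: Heteroscedasticity- and Censoring-Corrected Chromosome Partitioning Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chromosome partitioning analyses regress per-chromosome SNP
    heritability (h2c) on chromosome size to test for a polygenic trait
    architecture. Because h2c estimates are censored at zero and their
    standard errors grow with chromosome size, the usual one-tailed
    ordinary least squares slope test is anti-conservative. This package
    implements an HC-correction: a resampling-based null that draws h2c
    from Normal(0, SE) with censoring and computes an adaptive Monte
    Carlo corrected P value. It also ships a simulation engine
    (linkage-equilibrium genotypes, additive phenotypes, per-chromosome
    genomic relationship matrices and single-GRM REML via spectral
    decomposition), a phenotype-permutation null for cross-validation,
    readers for per-chromosome heritability tables and GCTA .hsq output,
    and QQ-based inflation-factor estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
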