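Package: omicblup
Title: Multi-Kernel BLUP for Phenotype Prediction from Genomic and Transcriptomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kernel-based phenotype prediction for panels of inbred lines.
    Implements genomic BLUP (GBLUP), transcriptomic BLUP with a linear kernel
    (TBLUP), reproducing kernel Hilbert space regression with a Gaussian kernel
    (RKHS), and the two-kernel combinations GTBLUP and GRBLUP. Variance
    components are estimated by average-information REML with an EM fallback;
    held-out lines are predicted by kernel-extended BLUP. Includes
    omics-augmented broad-sense heritability estimators, replicated k-fold
    cross-validation with Gaussian-bandwidth grid search, Tukey HSD model
    comparison, and a simulator of inbred-line genotypes, genotype-driven
    expression (with additive-by-additive epistasis) and phenotypes with
    controllable variance shares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse,
    yaml
Config/testthat/edition: 3
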