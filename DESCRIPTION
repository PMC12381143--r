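Package: stratomics
Title: Spatial Multi-Omics Integration of Compartmentalized Transcriptomes and Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartment-resolved integration of RNA-seq counts and
    data-independent-acquisition proteomics across microdissected brain
    subregions and laminae. Provides median-of-ratios size-factor
    normalization, robust-linear-regression (rlr) normalization of log2
    intensities, iBAQ transformation via in-silico Trypsin/P digestion,
    negative-binomial Wald differential enrichment for counts, empirical-Bayes
    moderated linear models for protein intensities, sorted-synaptosome
    contaminant filtering, mRNA-protein profile-correlation classification
    with protein half-life rank tests, co-enrichment and translatome mapping,
    hypergeometric gene-set overrepresentation, and NIPALS PLS-DA with VIP
    scores and cross-validated component selection. A synthetic-data
    generator with planted ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2,
    limma
Config/testthat/edition: 3
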