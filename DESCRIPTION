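Package: melanochip
Title: Hydrogel Biochip Genotyping of Melanoma Driver Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for an allele-specific hybridization
    biochip that genotypes 39 recurrent somatic mutations in the BRAF, NRAS,
    KIT, GNAQ, GNA11, MAP2K1 and MAP2K2 genes of melanoma samples. Provides
    the mutation panel with HGVS coding-change validation, a ground-truthed
    simulator of LNA-clamp enriched PCR, probe hybridization and 16-bit chip
    images, marker-based grid location and spot quantification, the
    background-normalized signal (J) mutation-calling rule, limit-of-detection
    estimation from dilution series, and cohort-level frequency, concordance
    and association statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    Biostrings,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
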