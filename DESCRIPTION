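Package: segdosage
Title: Dosage Analysis of Segmental Duplications from Expression Ratios and qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the transcriptional consequences of a
    segmental duplication. Computes per-gene variant/control expression
    ratios from FPKM tables, sliding-window median profiles along
    chromosomes, binned ratio distributions, dosage-effect and
    dosage-compensation classification, and region-stratified summary
    tables; applies Kolmogorov-Smirnov and Fisher's exact tests across
    chromosome regions; localizes duplication breakpoints from ordered
    qPCR marker panels via 2^-ddCt relative quantification and
    step-changepoint fitting; and includes a seeded synthetic-data
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
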