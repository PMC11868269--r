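Package: refstab
Title: Reference-Gene Stability Evaluation for qRT-PCR Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for selecting stable reference genes (including reference
    miRNAs) for qRT-PCR normalization. Provides a validated data model for
    replicated quantification-cycle (Ct) tables with sample metadata,
    technical-replicate quality control, standard-curve estimation of
    amplification efficiency, the four standard stability algorithms
    (comparative delta-Ct, geNorm with pairwise-variation analysis,
    NormFinder, and BestKeeper), geometric-mean rank aggregation across
    methods and experimental conditions, 2^-ddCt relative-expression
    validation of chosen normalizers, and a variance-component simulator of
    Ct experiments with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
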