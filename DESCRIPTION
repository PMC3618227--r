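Package: somatier
Title: Somatic Variant Tiering and Integrative Tumor Genome Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream analysis of paired tumor-normal whole-genome and
    transcriptome sequencing for a single case: somatic-score filtering with
    truth-set calibration, known-SNP exclusion, tier 1-4 variant
    classification, transcript consequence annotation, rank-based copy-number
    segmentation with arm-level event calling and SNP-depletion comparison,
    discordant-read structural-variant filtering with fusion-transcript
    orientation, premature-stop and nonsense-mediated-decay prediction, and
    integration of mutant-allele expression from RNA pileups. Includes a
    deterministic synthetic-data generator that emulates every input the
    pipeline consumes, so the whole analysis is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
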