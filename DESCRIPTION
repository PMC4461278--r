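Package: amperr
Title: Error Profiling for Amplicon Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates platform-specific sequencing error profiles from
    amplicon deep-sequencing runs. Provides quality masking and filtering of
    FASTQ reads, barcode demultiplexing and construct trimming for two-step
    PCR libraries, local alignment of insert reads against an amplicon
    reference panel, and estimation of substitution and indel error rates
    per run and per amplicon together with a base-specific substitution
    matrix that excludes homopolymeric and GC-rich reference regions. A
    read simulator with platform-style error models and full ground-truth
    logging supports validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
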