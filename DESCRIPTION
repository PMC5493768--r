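Package: hmcoloc
Title: Integrative 5hmC, Transcription-Factor and Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links 5-hydroxymethylcytosine (5hmC) dynamics and transcription
    factor promoter binding to transcriptome changes between two conditions.
    Provides strict readers for BED tag/peak files, gene models and
    differential-expression tables; strand-aware promoter, gene-body and
    flank regions; reads-per-million quantification and scaled metagene
    profiles (fixed-width flanks, percent-of-gene body bins); per-gene
    condition-ratio classification with exact binomial tests; peak proximity
    co-localization tests against a genome-coverage null; Welch cohort
    comparisons; hypergeometric over-representation analysis; a synthetic
    tag/peak/DE simulator with planted co-regulation structure and
    truth-based recovery scoring; and a deterministic end-to-end pipeline
    report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
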