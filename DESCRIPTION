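Package: prodomainevo
Title: Pro-Domain Conservation, NLS Motif-Loss Classification and
    Proximity-Labelling Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying convergent loss of the
    pro-interleukin-1-alpha nuclear localisation signal (NLS) across
    mammalian orthologs, and for differential enrichment of TurboID
    proximity-labelling proteomics. Provides modal-consensus conservation
    scoring of ortholog alignments with domain-level summaries, KKRR-motif
    extraction and loss classification, a sequencing-read base-vote
    procedure that dates motif-loss events from local alignments of reads
    to an exon query, and a Perseus-style label-free quantification (LFQ)
    pipeline (row filtering, log2 transform, validity filtering,
    downshifted-normal imputation, PCA, s0-moderated two-sample statistic
    with permutation false-discovery-rate control). Seeded synthetic-data
    generators make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
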