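Package: beamplicon
Title: Quantification of Base-Editing Outcomes from Targeted Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify CRISPR base-editing outcomes from targeted amplicon
    deep-sequencing reads: adapter trimming, semi-global affine-gap alignment of reads
    to an amplicon reference, per-protospacer-position conversion matrices and editing
    efficiencies, indel frequencies, allele tables with exclusive/combined (simultaneous
    A-to-G and C-to-T) edit classification for dual base editors, editing-window
    summaries and editor-vs-editor comparison statistics, and a filtering pipeline for
    RNA off-target variant tables with strand-aware A-to-I / C-to-U labeling. Includes
    a parameterized simulator of edited amplicon read populations and RNA variant
    tables that provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
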