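Package: translatome
Title: Polysome-Profiling Translatome Analysis with Two-Channel Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of translation efficiency from polysome-profiling
    two-channel microarrays: background correction (none, half, normexp),
    per-gene M/A summarization, stress translation-class calling
    (sensitive / resistant / inducible), translatome-transcriptome
    coordination, cross-species ortholog agreement stratified by abundance,
    mRNA sequence-feature reports (UTR/CDS lengths, G+C, upstream AUGs,
    start-codon context), equilibrium base-pair probability profiles via a
    McCaskill partition-function recursion under a pair-weight model, and
    gene-set enrichment by Fisher exact tests on single selections or on
    partitions of a ranked list. Includes a calibrated synthetic-data
    generator with per-transcript ground truth so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
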