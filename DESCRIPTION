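Package: dimorphatac
Title: Sex-Dimorphic Chromatin Accessibility Analysis with Stratified Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale pipeline for genome-wide analysis of sexually
    dimorphic chromatin accessibility in fruitless-expressing Drosophila
    neurons. Implements local-background Poisson peak calling on ATAC-seq
    fragment coverage, negative-binomial differential accessibility with
    chromosome-stratified (X versus autosome) normalization to remove
    X-dosage artifacts, direction-concordant intersection of comparisons to
    define condition-specific regulatory elements, peak-to-gene annotation
    and hypergeometric term enrichment, relative-distance statistics to
    dosage-compensation tether sites, gene-scale coverage analytics, an
    expression arm (TPM, differential expression, neighbor-gene bias test),
    and PWM motif scanning with exact score-distribution p-values. A
    negative-binomial fragment simulator with planted ground truth makes
    every stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
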