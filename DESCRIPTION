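Package: mutsigcnv
Title: Mutational Spectra and Consensus Copy-Number Calling for
    Drug-Selected Cancer Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterises genomic changes acquired by cancer cell lines
    under long-term drug selection. Extracts novel variants against a
    matched parental line (key subtraction, 10% variant-allele-fraction
    filter, adjacent-SNV merging), builds 96-trinucleotide mutational
    spectra under the pyrimidine convention and compares them by cosine
    similarity, and calls copy-number gains and losses from two-colour
    array-CGH log-ratios with a three-method consensus (circular binary
    segmentation, Haar-wavelet breakpoint detection and penalized optimal
    partitioning) calibrated by the derivative log ratio spread, with
    cross-sample penetrance summaries. A seeded simulator generates
    genomes, gene annotation, parental/treated variant-catalog pairs and
    probe arrays with planted truth so every stage can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
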