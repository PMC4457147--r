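Package: defensescan
Title: Genome-Defense Analytics for Fungal Genomes: RIP, DNA Methylation
    and Small-RNA Silencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects repeat-induced point mutation (RIP) in repeat
    families by alignment against an inferred pre-RIP consensus, computes
    the mutation spectrum, dinucleotide preference and composite RIP index
    (CRI) in sliding windows, scores per-cytosine bisulfite calls by
    sequence context (CpG/CHG/CHH) and per-feature methylation levels,
    calls microRNA-like (milRNA) and dicer-independent siRNA (disiRNA)
    loci from strand-specific small-RNA alignments with hairpin MFE/MFEI
    evaluation, and integrates RIP, methylation and expression evidence
    into transposable-element silencing cross-tabulations.  A synthetic
    genome simulator plants ground truth for every stage so the whole
    pipeline is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
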