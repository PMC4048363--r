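Package: plantmir
Title: Plant miRNA Discovery, Conservation, Target and Expression
    Analysis from Small RNA and Degradome Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for annotating plant microRNAs from
    high-throughput small RNA sequencing. Implements adapter trimming and
    tag collapsing, exact genome mapping with copy-number and ncRNA decoy
    filters, hairpin folding (thermodynamic engine with a base-pair
    maximisation fallback) and miRNA/miRNA* duplex evaluation under the
    classical plant miRNA annotation criteria (2-nt 3' overhangs, limited
    mismatches and asymmetric bulges, read dominance), cross-species
    conservation classification, degradome (PARE) based cleavage-site
    calling with Allen-style target alignment scoring and t-plots, ORF
    based cleavage-region classification, and RP10M expression profiling
    with hierarchical clustering. Ships a seeded synthetic-data generator
    that plants hairpin loci, decoy repeats, tissue-structured libraries
    and degradome peaks with labelled truth for validating every step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    ape,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
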