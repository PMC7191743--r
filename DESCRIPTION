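Package: circkit
Title: Downstream Analysis of Circular RNA Back-Spliced Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Harmonizes back-splice-junction (BSJ) predictions from multiple
    circular RNA detection tools into one canonical table, then annotates each
    junction against a gene model, filters on read-count prevalence, tests for
    differential expression with a negative-binomial Wald model, lifts
    coordinates across species through UCSC chain files, extracts
    circular-topology sequences, and screens them for RNA-binding-protein
    motifs, miRNA seed sites with G:U wobble rules, GWAS SNPs and inverted
    repeat pairs. Ships a deterministic synthetic fixture generator (mini
    genome, GTF, tool outputs in six dialects, motif/miRNA/SNP/repeat/chain
    files) so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
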