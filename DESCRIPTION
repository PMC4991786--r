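Package: nascentr
Title: Co-Transcriptional Splicing and RNA Polymerase II Elongation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects co-transcriptional splicing defects and RNA polymerase II
    elongation defects from genomic coverage tracks. Derives exon, intron and
    outron feature sets from GFF3/GTF annotations with minimum-length filters;
    computes per-gene mean feature coverage and pre-mRNA/mRNA ratio proxies;
    builds peak-masked, globally scaled coverage tracks; produces TSS- and
    TES-anchored metagene profiles with confidence intervals and a 3'/5'
    travelling-ratio summary; calls polymerase-bound genes from replicate peak
    files; tests gene-class enrichment among differentially expressed genes by
    the hypergeometric distribution; and quantifies transcript levels from qPCR
    Ct tables by the delta-delta-Ct method. Ships a deterministic synthetic
    nascent-transcription simulator (operons, trans-spliced outrons, programmed
    intron retention and polymerase gradients) so every stage is testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomeInfoDb,
    stats,
    utils,
    tools,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
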