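# Shared fixtures, built in code and memoized for the session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# two-gene toy annotation: a plus- and a minus-strand gene with the same
# exon layout (exons 101-160 and 201-300, intron 161-200)
toy_gtf <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.gtf")
  writeLines(c(
    'chr1\ttoy\tgene\t101\t300\t.\t+\t.\tgene_id "gplus"; transcript_id "gplus.t1";',
    'chr1\ttoy\texon\t101\t160\t.\t+\t.\tgene_id "gplus"; transcript_id "gplus.t1";',
    'chr1\ttoy\texon\t201\t300\t.\t+\t.\tgene_id "gplus"; transcript_id "gplus.t1";',
    'chr1\ttoy\tgene\t1101\t1300\t.\t-\t.\tgene_id "gminus"; transcript_id "gminus.t1";',
    'chr1\ttoy\texon\t1101\t1160\t.\t-\t.\tgene_id "gminus"; transcript_id "gminus.t1";',
    'chr1\ttoy\texon\t1201\t1300\t.\t-\t.\tgene_id "gminus"; transcript_id "gminus.t1";'),
    path)
  path
}

# in-memory gene models without going through a file
toy_models <- function(exon_starts, exon_ends, strand = "+", chrom = "chr1",
                       gene_id = "g1") {
  exons <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(exon_starts, exon_ends),
                                  strand = strand)
  genes <- range(exons)
  names(genes) <- gene_id
  S4Vectors::mcols(genes)$gene_id <- gene_id
  S4Vectors::mcols(genes)$tss <- if (strand == "+") GenomicRanges::start(genes)
                                 else GenomicRanges::end(genes)
  S4Vectors::mcols(genes)$tes <- if (strand == "+") GenomicRanges::end(genes)
                                 else GenomicRanges::start(genes)
  S4Vectors::mcols(genes)$operon_id <- NA_character_
  S4Vectors::mcols(genes)$biotype <- NA_character_
  exl <- GenomicRanges::GRangesList(list(exons))
  names(exl) <- gene_id
  introns <- GenomicRanges::psetdiff(genes, exl)
  nascentr:::new_gene_models(genes, exl, introns, GenomicRanges::GRanges())
}

flat_track <- function(value, len = 10000, chrom = "chr1", assay = "rna",
                       read_length = 100, condition = "") {
  coverage_track(stats::setNames(list(S4Vectors::Rle(value, len)), chrom),
                 assay = assay, read_length = read_length,
                 condition = condition)
}

small_config <- function(seed = 42, n_genes = 60, ...) {
  frac <- c(ubiquitous = 0.13, germline_enriched = 0.11,
            germline_specific = 0.10, soma_specific = 0.13,
            embryo_expressed = 0.20, chrX = 0.10, silent = 0.08)
  counts <- floor(frac * n_genes)
  counts[counts < 1] <- 1
  sim_config(seed = seed, n_genes = n_genes, class_counts = counts, ...)
}

shared_sim <- function() memo("sim", function() simulate_genome(small_config()))

shared_bundle <- function() memo("bundle", function() {
  dir <- file.path(tempdir(), "nascentr_bundle")
  suppressMessages(emit_fixture_bundle(small_config(), dir, overwrite = TRUE))
  dir
})

bundle_sim <- function() memo("bundle_sim", function() {
  shared_bundle()
  simulate_genome(small_config())
})
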