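#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlevels seqlengths
NULL

#' Gene model container
#'
#' Bundles per-gene structure derived from an annotation: the gene-body span,
#' ordered exons, the introns derived as the gaps between consecutive exons,
#' and (optionally) an outron — the nascent-transcript segment between an
#' experimentally defined transcription start site and the trans-splice
#' acceptor at the 5' edge of the first exon.
#'
#' All coordinates are 1-based closed (`GRanges` convention); BED input/output
#' converts at the boundary.
#'
#' @param genes `GRanges` of gene bodies, names = gene ids, with metadata
#'   columns `gene_id`, `tss`, `tes`, `operon_id`, `biotype`.
#' @param exons,introns `GRangesList` keyed by gene id, sorted by start.
#' @param outrons `GRanges` keyed (named) by gene id; possibly empty.
#' @return An object of class `GeneModels`.
#' @keywords internal
new_gene_models <- function(genes, exons, introns, outrons) {
  stopifnot(is(genes, "GRanges"), is(exons, "GRangesList"),
            is(introns, "GRangesList"), is(outrons, "GRanges"))
  obj <- structure(list(genes = genes, exons = exons, introns = introns,
                        outrons = outrons), class = "GeneModels")
  validate_gene_models(obj)
}

validate_gene_models <- function(x) {
  ids <- names(x$genes)
  if (is.null(ids) || anyDuplicated(ids))
    stop("gene ids must be unique and set as names")
  if (!identical(ids, names(x$exons)))
    stop("exons must be keyed identically to genes")
  if (any(as.character(strand(x$genes)) == "*"))
    stop("validation error: unknown strand for gene(s) ",
         paste(head(ids[as.character(strand(x$genes)) == "*"], 3), collapse = ", "))
  ex <- x$exons
  n_ex <- S4Vectors::elementNROWS(ex)
  if (any(n_ex == 0)) stop("every gene needs at least one exon")
  # exons sorted, disjoint, within span
  ue <- unlist(ex, use.names = FALSE)
  gene_of_exon <- rep(seq_along(ex), n_ex)
  span <- x$genes[gene_of_exon]
  if (any(start(ue) < start(span)) || any(end(ue) > end(span)))
    stop("validation error: exon outside gene span for gene(s) ",
         paste(unique(ids[gene_of_exon[start(ue) < start(span) | end(ue) > end(span)]]),
               collapse = ", "))
  if (length(x$outrons)) {
    oid <- names(x$outrons)
    if (!all(oid %in% ids)) stop("outron for unknown gene")
    first5 <- ifelse(as.character(strand(x$genes[oid])) == "+",
                     start(x$genes[oid]), end(x$genes[oid]))
    plus <- as.character(strand(x$genes[oid])) == "+"
    ok <- ifelse(plus, end(x$outrons) + 1L == first5, start(x$outrons) - 1L == first5)
    if (!all(ok)) stop("outron must abut the first exon's 5' edge")
  }
  x
}

#' @export
print.GeneModels <- function(x, ...) {
  cat(sprintf("GeneModels: %d genes, %d with outrons, on %d sequence(s)\n",
              length(x$genes), length(x$outrons),
              length(unique(as.character(seqnames(x$genes))))))
  invisible(x)
}

#' @export
length.GeneModels <- function(x) length(x$genes)

#' Gene ids of a GeneModels object
#' @param models A `GeneModels` object.
#' @return Character vector of gene ids.
#' @export
gene_ids <- function(models) names(models$genes)

#' Strand-aware TSS / TES positions
#'
#' The TSS is the genomic coordinate of the annotated 5' end of the gene body
#' (the trans-splice acceptor for outron-bearing genes), the TES the 3' end.
#'
#' @param models A `GeneModels` object.
#' @return Named integer vector of genomic positions.
#' @export
tss_positions <- function(models) {
  g <- models$genes
  stats::setNames(ifelse(as.character(strand(g)) == "+", start(g), end(g)),
                  names(g))
}

#' @rdname tss_positions
#' @export
tes_positions <- function(models) {
  g <- models$genes
  stats::setNames(ifelse(as.character(strand(g)) == "+", end(g), start(g)),
                  names(g))
}

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "gtf") return("gtf")
  if (ext %in% c("gff", "gff3")) return("gff3")
  # sniff column 9: GTF uses `key "value";`, GFF3 uses `key=value`
  ln <- readLines(path, n = 200L)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) stop("cannot guess annotation dialect of empty file: ", path)
  attr9 <- vapply(strsplit(ln, "\t", fixed = TRUE), function(f)
    if (length(f) >= 9) f[9] else "", character(1))
  if (any(grepl("\\w+ \"", attr9))) "gtf" else "gff3"
}

check_annotation_lines <- function(path) {
  ln <- readLines(path)
  body <- !startsWith(ln, "#") & nzchar(ln)
  nf <- lengths(strsplit(ln[body], "\t", fixed = TRUE))
  bad <- which(body)[nf < 8]
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected >= 8 tab-separated fields",
                 bad[1], path))
  invisible(TRUE)
}

#' Parse a gene annotation into gene models
#'
#' Reads GFF3 or GTF (1-based inclusive coordinates, per the formats), derives
#' introns as the gaps between consecutive exons, and optionally attaches
#' outrons from a file of experimentally defined (e.g. GRO-seq) transcription
#' start sites upstream of the annotated gene start.
#'
#' By default exons of all transcripts of a gene are collapsed (overlapping
#' records merged) before intron derivation, so features are counted once per
#' gene. With `collapse_transcripts = FALSE` one model is built per transcript
#' (model id = transcript id) and features are counted per transcript.
#'
#' @param path Annotation file (GFF3 or GTF).
#' @param dialect `"auto"` (default), `"gff3"` or `"gtf"`.
#' @param tss_override Optional BED file (0-based half-open) or `GRanges` whose
#'   name field matches gene ids; each entry places the nascent TSS upstream of
#'   the annotated gene start and defines the outron as the interval from that
#'   TSS to the first exon's 5' edge in transcript orientation.
#' @param collapse_transcripts Collapse transcripts to their exon union per
#'   gene (default `TRUE`).
#' @return A `GeneModels` object.
#' @export
parse_annotation <- function(path, dialect = c("auto", "gff3", "gtf"),
                             tss_override = NULL, collapse_transcripts = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "auto") dialect <- guess_dialect(path)
  check_annotation_lines(path)
  gr <- rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "gff3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (!length(ex)) stop("no exon records found in ", path)

  if (dialect == "gtf") {
    gene_of <- as.character(ex$gene_id)
    tx_of <- if (!is.null(ex$transcript_id)) as.character(ex$transcript_id) else gene_of
  } else {
    parent <- as.character(vapply(ex$Parent, `[`, character(1), 1))
    # map transcript-level parents up to genes where such records exist
    feat_id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
    tx_idx <- match(parent, feat_id)
    up <- rep(NA_character_, length(ex))
    has_tx <- !is.na(tx_idx)
    if (any(has_tx)) {
      txp <- gr$Parent[tx_idx[has_tx]]
      up[has_tx] <- vapply(txp, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                           character(1))
    }
    gene_of <- ifelse(is.na(up), parent, up)
    gene_of <- sub("^gene:", "", gene_of)
    tx_of <- sub("^transcript:", "", parent)
  }
  if (anyNA(gene_of)) stop("exon records without resolvable gene id in ", path)

  key <- if (collapse_transcripts) gene_of else tx_of
  ex_by <- S4Vectors::split(granges(ex), key)
  ex_by <- GRangesList(lapply(ex_by, function(g) sort(reduce(g))))

  strands <- vapply(ex_by, function(g) {
    s <- unique(as.character(strand(g)))
    if (length(s) != 1) "*" else s
  }, character(1))
  if (any(strands == "*"))
    stop("validation error: unknown or mixed strand for gene(s) ",
         paste(head(names(ex_by)[strands == "*"], 3), collapse = ", "))

  span <- unlist(range(ex_by))
  # explicit gene records constrain the span and catch stray exons
  gene_rec <- gr[tolower(as.character(gr$type)) == "gene"]
  if (length(gene_rec) && collapse_transcripts) {
    gid <- if (dialect == "gtf") as.character(gene_rec$gene_id)
           else sub("^gene:", "", as.character(gene_rec$ID))
    hit <- match(names(span), gid)
    ok <- !is.na(hit)
    if (any(start(span[ok]) < start(gene_rec[hit[ok]]) |
            end(span[ok]) > end(gene_rec[hit[ok]])))
      stop("validation error: exon outside annotated gene span")
    start(span[ok]) <- start(gene_rec[hit[ok]])
    end(span[ok]) <- end(gene_rec[hit[ok]])
  }
  introns <- psetdiff(span, ex_by)

  plus <- strands == "+"
  mcols(span)$gene_id <- names(span)
  mcols(span)$tss <- ifelse(plus, start(span), end(span))
  mcols(span)$tes <- ifelse(plus, end(span), start(span))
  mcols(span)$operon_id <- extract_gene_attr(gr, ex, key, "operon_id", dialect)[names(span)]
  mcols(span)$biotype <- extract_gene_attr(gr, ex, key, "gene_biotype", dialect)[names(span)]

  outrons <- GRanges()
  if (!is.null(tss_override)) {
    ov <- if (is(tss_override, "GRanges")) tss_override
          else rtracklayer::import(tss_override, format = "bed")
    onames <- if (!is.null(ov$name)) as.character(ov$name) else names(ov)
    keep <- onames %in% names(span)
    ov <- ov[keep]; onames <- onames[keep]
    if (length(ov)) {
      g <- span[onames]
      gplus <- as.character(strand(g)) == "+"
      pos <- ifelse(gplus, start(ov), end(ov))
      upstream <- ifelse(gplus, pos < start(g), pos > end(g))
      if (!all(upstream))
        stop("validation error: tss_override not upstream of annotated start for gene(s) ",
             paste(head(onames[!upstream], 3), collapse = ", "))
      outrons <- GRanges(seqnames(g),
                         IRanges(ifelse(gplus, pos, end(g) + 1L),
                                 ifelse(gplus, start(g) - 1L, pos)),
                         strand = strand(g))
      names(outrons) <- onames
    }
  }
  new_gene_models(span, ex_by, introns, outrons)
}

extract_gene_attr <- function(gr, ex, key, attr, dialect) {
  out <- stats::setNames(rep(NA_character_, length(unique(key))), unique(key))
  if (!is.null(mcols(ex)[[attr]])) {
    v <- tapply(as.character(mcols(ex)[[attr]]), key, function(z) z[!is.na(z)][1])
    out[names(v)] <- unname(v)
  }
  out
}

#' Write gene models back to GTF
#'
#' Emits one `gene` record and per-exon `exon` records per gene, 1-based
#' inclusive. Re-parsing the file yields identical coordinates.
#'
#' @param models A `GeneModels` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  g <- models$genes
  lines <- character(0)
  for (i in seq_along(g)) {
    id <- names(g)[i]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";', id, id)
    op <- mcols(g)$operon_id[i]
    if (!is.na(op)) attrs <- paste0(attrs, sprintf(' operon_id "%s";', op))
    bt <- mcols(g)$biotype[i]
    if (!is.na(bt)) attrs <- paste0(attrs, sprintf(' gene_biotype "%s";', bt))
    chr <- as.character(seqnames(g))[i]
    str <- as.character(strand(g))[i]
    lines <- c(lines,
               sprintf("%s\tnascentr\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       chr, start(g)[i], end(g)[i], str, attrs))
    e <- models$exons[[id]]
    lines <- c(lines,
               sprintf("%s\tnascentr\texon\t%d\t%d\t.\t%s\t.\t%s",
                       chr, start(e), end(e), str, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive the length-filtered feature catalog
#'
#' Applies the minimum feature length filter to exons and introns (features
#' shorter than `min_length` are dropped) and reports genome-wide retained
#' counts. Outrons are never length-filtered; they are carried on the models.
#'
#' @param models A `GeneModels` object (possibly empty).
#' @param min_length Minimum feature length in bases (default 50).
#' @return A `FeatureCatalog`: list with `exons` and `introns` (`GRanges` with
#'   metadata columns `gene_id` and `index`, the ordinal of the feature within
#'   its gene in genomic order before filtering), retained counts `n_exons`,
#'   `n_introns`, and `min_length`.
#' @export
derive_features <- function(models, min_length = 50) {
  stopifnot(min_length >= 1)
  flatten <- function(grl) {
    n <- S4Vectors::elementNROWS(grl)
    u <- unlist(grl, use.names = FALSE)
    if (length(u)) {
      mcols(u)$gene_id <- rep(names(grl), n)
      mcols(u)$index <- unlist(lapply(n, seq_len), use.names = FALSE)
    } else {
      mcols(u)$gene_id <- character(0)
      mcols(u)$index <- integer(0)
    }
    u[width(u) >= min_length]
  }
  ex <- flatten(models$exons)
  int <- flatten(models$introns)
  structure(list(exons = ex, introns = int,
                 n_exons = length(ex), n_introns = length(int),
                 min_length = min_length),
            class = "FeatureCatalog")
}

#' Genome-wide retained feature counts
#' @param catalog A `FeatureCatalog`.
#' @return Named integer vector `c(n_exons, n_introns)`.
#' @export
count_features <- function(catalog) {
  stopifnot(inherits(catalog, "FeatureCatalog"))
  c(n_exons = catalog$n_exons, n_introns = catalog$n_introns)
}

#' @export
print.FeatureCatalog <- function(x, ...) {
  cat(sprintf("FeatureCatalog: %d exons, %d introns retained (min length %d bp)\n",
              x$n_exons, x$n_introns, x$min_length))
  invisible(x)
}

#' Write a feature catalog as BED
#'
#' BED6, 0-based half-open, name field `gene_id|feature_type|index`.
#'
#' @param catalog A `FeatureCatalog`.
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
write_feature_bed <- function(catalog, path) {
  fmt <- function(gr, type) {
    if (!length(gr)) return(character(0))
    sprintf("%s\t%d\t%d\t%s|%s|%d\t0\t%s",
            as.character(seqnames(gr)), start(gr) - 1L, end(gr),
            mcols(gr)$gene_id, type, mcols(gr)$index, as.character(strand(gr)))
  }
  writeLines(c(fmt(catalog$exons, "exon"), fmt(catalog$introns, "intron")), path)
  invisible(path)
}

#' Write the retained-count summary
#' @param catalog A `FeatureCatalog`.
#' @param path Output tab-separated file.
#' @return `path`, invisibly.
#' @export
write_feature_summary <- function(catalog, path) {
  utils::write.table(
    data.frame(min_length = catalog$min_length,
               n_exons = catalog$n_exons, n_introns = catalog$n_introns),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
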