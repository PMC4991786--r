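#' Coverage track container
#'
#' Per-chromosome, per-base signal held as run-length encoded vectors, with
#' the metadata needed for normalization: the assay (RNA-seq or ChIP-seq), the
#' nominal read length used to convert base-coverage to read-equivalents, and
#' an optional mask of regions excluded from totals (e.g. polymerase peak
#' regions during between-sample scaling).
#'
#' @param cov Named `RleList`-like list of numeric `Rle`, one per chromosome.
#' @param sample_label,condition Free-text labels.
#' @param assay `"rna"` or `"chip"`.
#' @param read_length Nominal read length in bases (default 100).
#' @param mask Optional `GRanges` excluded from totals.
#' @return An object of class `CoverageTrack`.
#' @export
coverage_track <- function(cov, sample_label = "", condition = "",
                           assay = c("rna", "chip"), read_length = 100,
                           mask = NULL) {
  assay <- match.arg(assay)
  if (!is(cov, "RleList")) cov <- methods::as(cov, "RleList")
  if (length(cov) && (is.null(names(cov)) || !all(nzchar(names(cov)))))
    stop("coverage list must be named by chromosome")
  if (any(vapply(cov, function(r) length(r) && min(S4Vectors::runValue(r)) < 0,
                 logical(1))))
    stop("validation error: negative coverage values")
  structure(list(cov = cov, sample_label = sample_label, condition = condition,
                 assay = assay, read_length = read_length,
                 mask = if (!is.null(mask)) reduce(unstrand(mask)) else NULL),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack [%s] %s/%s: %d chromosome(s), %.0f read-equivalents%s\n",
              x$assay, x$sample_label, x$condition, length(x$cov),
              track_read_total(x),
              if (is.null(x$mask)) "" else sprintf(" (%d masked regions)",
                                                   length(x$mask))))
  invisible(x)
}

chrom_lengths_of <- function(track) vapply(track$cov, length, integer(1))

# 0/1 mask coverage per chromosome, matched to track geometry
mask_rle <- function(track) {
  stopifnot(!is.null(track$mask))
  lens <- chrom_lengths_of(track)
  m <- track$mask
  GenomeInfoDb::seqlevels(m) <- union(GenomeInfoDb::seqlevels(m), names(lens))
  cv <- coverage(m, width = as.list(lens))[names(lens)]
  methods::as(lapply(cv, function(r) Rle(as.integer(S4Vectors::runValue(r) > 0),
                                         S4Vectors::runLength(r))), "RleList")
}

sum_over <- function(cov, gr) {
  total <- 0
  for (chr in unique(as.character(seqnames(gr)))) {
    r <- ranges(gr[as.character(seqnames(gr)) == chr])
    if (!chr %in% names(cov)) stop("interval on unknown chromosome: ", chr)
    if (length(r) && max(end(r)) > length(cov[[chr]]))
      stop("interval beyond chromosome bounds on ", chr)
    total <- total + sum(viewSums(Views(cov[[chr]], r)))
  }
  total
}

#' Load a coverage track from bedGraph or read intervals
#'
#' bedGraph records are expanded to per-base signal; BED read intervals are
#' stacked (each read contributes 1 over its span). Bases not covered by any
#' record are 0. Records on chromosomes absent from `chrom_lengths` (when
#' given) are skipped with a warning reporting the count.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"bedgraph"` or `"bed_reads"`.
#' @param read_length Nominal read length in bases (default 100).
#' @param chrom_lengths Optional named integer vector fixing chromosome
#'   lengths; inferred from the data otherwise.
#' @param sample_label,condition,assay Track metadata (see [coverage_track()]).
#' @return A `CoverageTrack`.
#' @export
load_track <- function(path, format = c("auto", "bedgraph", "bed_reads"),
                       read_length = 100, chrom_lengths = NULL,
                       sample_label = basename(path), condition = "",
                       assay = "rna") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(bedgraph|bg)(\\.gz)?$", tolower(path)))
      "bedgraph" else "bed_reads"
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bedgraph") "bedGraph" else "bed"),
    error = function(e) {
      if (file.exists(path) && file.size(path) == 0) GRanges() else stop(e)
    })
  if (format == "bedgraph" && length(gr) && !is.null(gr$score) &&
      any(gr$score < 0))
    stop("validation error: negative bedGraph value in ", path)
  if (!is.null(chrom_lengths)) {
    unknown <- !(as.character(seqnames(gr)) %in% names(chrom_lengths))
    if (any(unknown)) {
      warning(sprintf("skipped %d record(s) on unknown chromosome(s) in %s",
                      sum(unknown), path))
      gr <- gr[!unknown]
    }
    GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
    lens <- as.list(chrom_lengths)
  } else {
    lens <- lapply(split(end(gr), as.character(seqnames(gr))), max)
    lens <- lens[unique(as.character(seqnames(gr)))]
  }
  w <- if (format == "bedgraph" && length(gr) && !is.null(gr$score))
    gr$score else 1L
  cv <- if (length(gr) || length(lens))
    coverage(gr, width = lens, weight = w)
  else methods::as(list(), "RleList")
  coverage_track(methods::as(cv, "RleList"), sample_label = sample_label,
                 condition = condition, assay = assay,
                 read_length = read_length)
}

#' Unmasked read-equivalent total of a track
#'
#' Base-coverage summed outside the mask, divided by the nominal read length.
#'
#' @param track A `CoverageTrack`.
#' @return Read-equivalent total (numeric).
#' @export
track_read_total <- function(track) {
  total <- sum(vapply(track$cov, function(r) sum(as.numeric(r)), numeric(1)))
  if (!is.null(track$mask) && length(track$mask))
    total <- total - sum_over(track$cov, trim_to_track(track$mask, track))
  total / track$read_length
}

trim_to_track <- function(gr, track) {
  lens <- chrom_lengths_of(track)
  gr <- gr[as.character(seqnames(gr)) %in% names(lens)]
  end(gr) <- pmin(end(gr), lens[as.character(seqnames(gr))])
  gr[start(gr) <= end(gr)]
}

#' Mask peak regions and scale a track to a target read total
#'
#' Implements peak-masked global scaling: the read-equivalent total is
#' computed outside `mask_regions` (base-coverage divided by read length),
#' then every value in the track is multiplied by
#' `target_reads / unmasked_total`. Masked bases keep their scaled values for
#' inspection but stay excluded from any subsequent total. Defaults follow the
#' assay: ChIP tracks scale to 2 million reads, RNA tracks to 10 million.
#'
#' @param track A `CoverageTrack`.
#' @param mask_regions `GRanges` of regions to exclude from totals (e.g. the
#'   union of polymerase peak calls from all replicates of both conditions);
#'   may be empty.
#' @param target_reads Target read-equivalent total; default 2e6 for
#'   `assay = "chip"`, 1e7 for `assay = "rna"`.
#' @return A scaled `CoverageTrack` carrying the mask.
#' @export
mask_and_scale <- function(track, mask_regions = GRanges(),
                           target_reads = NULL) {
  if (is.null(target_reads))
    target_reads <- if (track$assay == "chip") 2e6 else 1e7
  stopifnot(target_reads > 0)
  masked <- coverage_track(track$cov, track$sample_label, track$condition,
                           track$assay, track$read_length,
                           mask = if (length(mask_regions)) mask_regions else NULL)
  tot <- track_read_total(masked)
  if (tot <= 0) stop("zero unmasked signal: scaling undefined")
  f <- target_reads / tot
  masked$cov <- methods::as(lapply(masked$cov, function(r) r * f), "RleList")
  masked
}

#' Length-weighted mean coverage over a set of intervals
#'
#' Total signal over the intervals divided by their total length. Overlapping
#' intervals are unioned first (set semantics); masked bases, when the track
#' carries a mask, are excluded from both numerator and denominator.
#'
#' @param track A `CoverageTrack`.
#' @param intervals `GRanges`, non-empty, within chromosome bounds.
#' @return Mean signal per base (numeric scalar).
#' @export
mean_feature_coverage <- function(track, intervals) {
  stopifnot(length(intervals) > 0)
  gr <- reduce(unstrand(granges(intervals)))
  if (!is.null(track$mask) && length(track$mask))
    gr <- GenomicRanges::setdiff(gr, unstrand(track$mask))
  if (!sum(width(gr))) return(NA_real_)
  sum_over(track$cov, gr) / sum(width(gr))
}

#' Per-gene exon / intron / outron mean coverage table
#'
#' One row per gene with at least one retained exon. Means are length-weighted
#' across the gene's retained features; genes without retained introns get
#' `NA` intron fields. Outron means are reported for outron-bearing genes.
#' Log2 columns are `log2(mean + pseudocount)`.
#'
#' @param track A `CoverageTrack`.
#' @param catalog A `FeatureCatalog` from [derive_features()].
#' @param models The `GeneModels` the catalog was derived from.
#' @param pseudocount Offset added before log2 (default 1).
#' @return `data.frame` with columns `gene_id`, `condition`, `mean_exon_cov`,
#'   `mean_intron_cov`, `mean_outron_cov` and their `log2_*` transforms.
#' @export
gene_feature_table <- function(track, catalog, models, pseudocount = 1) {
  stopifnot(inherits(catalog, "FeatureCatalog"), inherits(models, "GeneModels"))
  pooled <- function(gr) {
    if (!length(gr))
      return(stats::setNames(numeric(0), character(0)))
    sums <- widths <- numeric(length(gr))
    for (chr in unique(as.character(seqnames(gr)))) {
      i <- as.character(seqnames(gr)) == chr
      if (!chr %in% names(track$cov))
        stop("interval on unknown chromosome: ", chr)
      sums[i] <- viewSums(Views(track$cov[[chr]], ranges(gr[i])))
      widths[i] <- width(gr[i])
    }
    ids <- mcols(gr)$gene_id
    tapply(sums, ids, sum)[unique(ids)] / tapply(widths, ids, sum)[unique(ids)]
  }
  ex <- pooled(catalog$exons)
  int <- pooled(catalog$introns)
  og <- models$outrons
  if (length(og)) mcols(og)$gene_id <- names(og)
  out <- pooled(og)
  ids <- names(ex)
  res <- data.frame(
    gene_id = ids,
    condition = track$condition,
    mean_exon_cov = as.numeric(ex),
    mean_intron_cov = as.numeric(int[ids]),
    mean_outron_cov = as.numeric(out[ids]),
    stringsAsFactors = FALSE)
  res$log2_exon <- log2(res$mean_exon_cov + pseudocount)
  res$log2_intron <- log2(res$mean_intron_cov + pseudocount)
  res$log2_outron <- log2(res$mean_outron_cov + pseudocount)
  rownames(res) <- NULL
  res
}

#' Write a track as bedGraph
#'
#' Zero runs are omitted; coordinates are 0-based half-open per the format.
#'
#' @param track A `CoverageTrack`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chr in names(track$cov)) {
    r <- track$cov[[chr]]
    v <- S4Vectors::runValue(r)
    l <- S4Vectors::runLength(r)
    ends <- cumsum(as.numeric(l))
    starts <- ends - as.numeric(l)
    keep <- v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%.0f\t%.0f\t%s", chr, starts[keep], ends[keep],
                         formatC(v[keep], format = "g", digits = 10)), con)
  }
  invisible(path)
}
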