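#' Read a peak-call file
#'
#' Accepts BED and broadPeak (narrowPeak tolerated; extra columns ignored),
#' 0-based half-open on disk. Overlapping intervals within a replicate are
#' merged on load, with a message reporting how many were collapsed.
#'
#' @param path Peak file.
#' @param condition,replicate Labels carried on the set.
#' @param format `"auto"` (by extension), `"bed"` or `"broadpeak"`.
#' @param min_score Optional score filter: rows with column 5 below it are
#'   dropped (q-value filtering is the peak caller's job; this is a
#'   convenience escape hatch).
#' @return A `PeakSet`: list with `intervals` (`GRanges`), `condition`,
#'   `replicate`, `source_format`.
#' @export
read_peaks <- function(path, condition = "", replicate = "",
                       format = c("auto", "bed", "broadpeak"),
                       min_score = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(broadpeak|narrowpeak)$", tolower(path)))
      "broadpeak" else "bed"
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 3) stop("peak file needs at least chrom/start/end: ", path)
  if (!is.null(min_score) && ncol(tab) >= 5)
    tab <- tab[tab[[5]] >= min_score, , drop = FALSE]
  gr <- GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]))
  peak_set(gr, condition, replicate, format)
}

#' Construct a peak set
#' @param intervals `GRanges` of peak intervals.
#' @param condition,replicate,source_format Labels.
#' @return A `PeakSet`.
#' @export
peak_set <- function(intervals, condition = "", replicate = "",
                     source_format = "bed") {
  merged <- reduce(unstrand(intervals))
  n_merged <- length(intervals) - length(merged)
  if (n_merged > 0)
    message(sprintf("merged %d overlapping peak interval(s) (%s rep %s)",
                    n_merged, condition, replicate))
  structure(list(intervals = merged, condition = condition,
                 replicate = replicate, source_format = source_format),
            class = "PeakSet")
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet %s rep %s: %d intervals (%s)\n", x$condition,
              x$replicate, length(x$intervals), x$source_format))
  invisible(x)
}

#' Call polymerase-bound genes from two replicate peak sets
#'
#' A gene is called bound when its gene body (annotated span including
#' introns, excluding any outron) overlaps at least one peak — by at least
#' one base — in *both* replicates of the condition.
#'
#' @param rep1,rep2 `PeakSet`s from the same condition.
#' @param models A `GeneModels` object.
#' @return Character vector of bound gene ids.
#' @export
call_bound_genes <- function(rep1, rep2, models) {
  stopifnot(inherits(rep1, "PeakSet"), inherits(rep2, "PeakSet"))
  if (!identical(rep1$condition, rep2$condition))
    stop("replicates are from different conditions: '", rep1$condition,
         "' vs '", rep2$condition, "'")
  bodies <- unstrand(models$genes)
  hit1 <- countOverlaps(bodies, rep1$intervals) > 0
  hit2 <- countOverlaps(bodies, rep2$intervals) > 0
  names(bodies)[hit1 & hit2]
}

#' Write a gene list, one id per line
#' @param ids Character vector of gene ids.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read a gene list, one id per line
#' @param path Input file.
#' @return Character vector (empty lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}
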