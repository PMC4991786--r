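#' Read a differential-expression table
#'
#' Two layouts: `"standard"`, tab-separated with header columns `gene_id`,
#' `log2fc`, `q`; and `"cuffdiff"`, the Cuffdiff `gene_exp.diff` layout, from
#' which the `gene`, `log2(fold_change)` and `q_value` columns are mapped.
#'
#' @param path Input file.
#' @param layout `"standard"` (default) or `"cuffdiff"`.
#' @return `data.frame` with `gene_id`, `log2fc`, `q`.
#' @export
read_de_table <- function(path, layout = c("standard", "cuffdiff")) {
  layout <- match.arg(layout)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "cuffdiff") {
    need <- c("gene", "log2(fold_change)", "q_value")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("parse error: missing column(s) ",
                           paste(miss, collapse = ", "))
    tab <- data.frame(gene_id = tab$gene,
                      log2fc = as.numeric(tab[["log2(fold_change)"]]),
                      q = as.numeric(tab$q_value), stringsAsFactors = FALSE)
  } else {
    miss <- setdiff(c("gene_id", "log2fc", "q"), names(tab))
    if (length(miss)) stop("parse error: missing column(s) ",
                           paste(miss, collapse = ", "))
    tab <- tab[c("gene_id", "log2fc", "q")]
  }
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene ids in DE table")
  if (any(!is.na(tab$q) & (tab$q < 0 | tab$q > 1)))
    stop("q values must lie in [0, 1]")
  tab
}

#' Select differentially expressed gene sets
#'
#' Down = genes with `q <= max_q` and fold change at or below `1/min_fold`;
#' up = `q <= max_q` and fold change at or above `min_fold` (i.e.
#' `|log2fc| >= log2(min_fold)`). Rows sitting exactly on a threshold are
#' counted and reported via a message.
#'
#' @param table DE table (see [read_de_table()]).
#' @param min_fold Minimum fold change, > 1 (default 2).
#' @param max_q Maximum q-value (default 0.05).
#' @return List with character vectors `down` and `up`.
#' @export
select_de_genes <- function(table, min_fold = 2, max_q = 0.05) {
  stopifnot(min_fold > 1)
  l2 <- log2(min_fold)
  ok <- !is.na(table$log2fc) & !is.na(table$q) & table$q <= max_q
  boundary <- sum((!is.na(table$q) & table$q == max_q) |
                    (!is.na(table$log2fc) & abs(table$log2fc) == l2))
  if (boundary > 0)
    message(sprintf("%d row(s) sit exactly on a selection threshold", boundary))
  list(down = table$gene_id[ok & table$log2fc <= -l2],
       up = table$gene_id[ok & table$log2fc >= l2])
}

#' Build the gene-class catalog from published membership lists
#'
#' Combines tissue-expression source lists by set algebra into the analysis
#' classes: ubiquitous (expressed in the germline, neuronal, muscle and gut
#' sets), germline-enriched (source list minus spermatogenesis genes),
#' germline-specific (germline-expressed in either germline source,
#' intersected with the strict-maternal class, minus anything somatic),
#' soma-specific (any somatic set minus both germline sources),
#' embryo-expressed (the strict-embryonic class), chrX (all X-linked genes)
#' and silent.
#'
#' @param lists Named list of character vectors with roles `germline`,
#'   `neuronal`, `muscle`, `gut`, `somatic_any`, `germline_enriched_src`,
#'   `strict_maternal`, `strict_embryonic`, `chrX_all`, `silent_src`,
#'   `sperm_genes`.
#' @return A `GeneClassCatalog`: named list of gene-id vectors with classes
#'   `ubiquitous`, `germline_enriched`, `germline_specific`, `soma_specific`,
#'   `embryo_expressed`, `chrX`, `silent`. Classes may overlap.
#' @export
build_catalog <- function(lists) {
  roles <- c("germline", "neuronal", "muscle", "gut", "somatic_any",
             "germline_enriched_src", "strict_maternal", "strict_embryonic",
             "chrX_all", "silent_src", "sperm_genes")
  miss <- setdiff(roles, names(lists))
  if (length(miss)) stop("missing membership role(s): ",
                         paste(miss, collapse = ", "))
  l <- lapply(lists[roles], unique)
  cat <- list(
    ubiquitous = Reduce(intersect, l[c("germline", "neuronal", "muscle", "gut")]),
    germline_enriched = setdiff(l$germline_enriched_src, l$sperm_genes),
    germline_specific = setdiff(
      intersect(union(l$germline, l$germline_enriched_src), l$strict_maternal),
      l$somatic_any),
    soma_specific = setdiff(setdiff(l$somatic_any, l$germline),
                            l$germline_enriched_src),
    embryo_expressed = l$strict_embryonic,
    chrX = l$chrX_all,
    silent = l$silent_src)
  structure(cat, class = c("GeneClassCatalog", "list"))
}

#' One-sided hypergeometric enrichment / depletion probabilities
#'
#' Sampling `n` genes without replacement from a universe of `N` containing a
#' class of size `K` and observing `k` class members:
#' `p_enrich = P(X >= k)`, `p_deplete = P(X <= k)`. Both tails include the
#' point mass `P(X = k)`, so they sum to at least 1.
#'
#' @param N Universe size.
#' @param K Class size within the universe.
#' @param n Sample (e.g. DE set) size.
#' @param k Observed class members in the sample.
#' @return List with `p_enrich` and `p_deplete`.
#' @export
hypergeom_test <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N)
  if (k < max(0, n + K - N) || k > min(n, K))
    stop("domain error: k = ", k, " outside the support [",
         max(0, n + K - N), ", ", min(n, K), "]")
  list(p_enrich = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_deplete = stats::phyper(k, K, N - K, n, lower.tail = TRUE))
}

tier_for <- function(p) {
  if (p <= 1e-10) "***" else if (p <= 1e-5) "**" else if (p <= 0.01) "*" else ""
}

#' Gene-class enrichment report for a DE gene set
#'
#' For each class in the catalog (intersected with the universe first):
#' observed count among the DE set, expected count `n*K/N`, their ratio, and
#' one-sided hypergeometric enrichment and depletion p-values. Significance
#' tiers follow the convention `*` p <= 0.01, `**` p <= 1e-5, `***` p <=
#' 1e-10, applied to the smaller tail; `direction` records which tail won.
#' No multiple-testing correction is applied (raw tiers are reported).
#'
#' @param de_set Character vector of DE gene ids (subset of `universe`).
#' @param universe Character vector: genes with sufficient read representation
#'   in the DE analysis (not all annotated genes).
#' @param catalog A `GeneClassCatalog` (or any named list of id vectors).
#' @return `data.frame` with one row per class: `class`, `N`, `K`, `n`, `k`,
#'   `expected`, `obs_exp_ratio`, `p_enrich`, `p_deplete`, `direction`,
#'   `tier`.
#' @export
enrichment_report <- function(de_set, universe, catalog) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  de_set <- unique(de_set)
  if (!all(de_set %in% universe))
    stop("DE set contains genes outside the universe")
  N <- length(universe); n <- length(de_set)
  out <- do.call(rbind, lapply(names(catalog), function(cls) {
    members <- intersect(catalog[[cls]], universe)
    K <- length(members)
    k <- length(intersect(de_set, members))
    p <- hypergeom_test(N, K, n, k)
    expected <- n * K / N
    direction <- if (p$p_enrich <= p$p_deplete) "enriched" else "depleted"
    data.frame(class = cls, N = N, K = K, n = n, k = k,
               expected = expected,
               obs_exp_ratio = if (expected > 0) k / expected else NA_real_,
               p_enrich = p$p_enrich, p_deplete = p$p_deplete,
               direction = direction,
               tier = tier_for(min(p$p_enrich, p$p_deplete)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bar plot of observed vs expected class counts
#'
#' Observed and expected counts per gene class with the observed/expected
#' ratio and significance tier annotated.
#'
#' @param report Output of [enrichment_report()].
#' @param title Plot title.
#' @return A `ggplot` object.
#' @export
plot_enrichment <- function(report, title = "Gene-class enrichment") {
  long <- rbind(
    data.frame(class = report$class, what = "observed", count = report$k),
    data.frame(class = report$class, what = "expected",
               count = report$expected))
  lab <- sprintf("%.2f%s", report$obs_exp_ratio,
                 ifelse(report$tier == "", "",
                        paste0(" ", report$tier,
                               substr(report$direction, 1, 1))))
  ggplot2::ggplot(long, ggplot2::aes(x = class, y = count, fill = what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::annotate("text", x = report$class,
                      y = pmax(report$k, report$expected), label = lab,
                      vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "genes", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
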