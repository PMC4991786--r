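#' Pre-mRNA/mRNA ratio from feature coverage
#'
#' Uses intron (or outron) mean coverage as the unprocessed pre-mRNA proxy and
#' exon mean coverage as the mRNA proxy. For each gene present in both
#' conditions, reports the ratio per condition and the treatment/control
#' ratio change — a coverage analogue of qPCR amplicons targeting introns or
#' outrons versus spliced exon-exon junctions.
#'
#' @param treatment,control Per-gene coverage tables from
#'   [gene_feature_table()] for the two conditions.
#' @param numerator `"intron"` (default) or `"outron"`: the pre-mRNA proxy.
#' @return `data.frame` with `gene_id`, per-condition `premrna_signal`,
#'   `mrna_signal`, `ratio_treatment`, `ratio_control`, `ratio_change`
#'   (treatment ratio / control ratio) and a logical `excluded` flag for genes
#'   whose control mRNA signal is 0 or whose numerator is missing
#'   (`ratio_change` is `NA` for those; they are dropped from summaries).
#' @export
splicing_ratio <- function(treatment, control, numerator = c("intron", "outron")) {
  numerator <- match.arg(numerator)
  num_col <- paste0("mean_", numerator, "_cov")
  common <- intersect(treatment$gene_id, control$gene_id)
  if (!length(common)) stop("mismatched gene ids: no gene in both conditions")
  t <- treatment[match(common, treatment$gene_id), ]
  c0 <- control[match(common, control$gene_id), ]
  res <- data.frame(
    gene_id = common,
    numerator = numerator,
    premrna_treatment = t[[num_col]],
    mrna_treatment = t$mean_exon_cov,
    premrna_control = c0[[num_col]],
    mrna_control = c0$mean_exon_cov,
    stringsAsFactors = FALSE)
  res$ratio_treatment <- res$premrna_treatment / res$mrna_treatment
  res$ratio_control <- res$premrna_control / res$mrna_control
  res$excluded <- is.na(res$premrna_treatment) | is.na(res$premrna_control) |
    is.na(res$mrna_control) | res$mrna_control == 0 |
    res$mrna_treatment == 0 | res$ratio_control == 0
  res$ratio_change <- ifelse(res$excluded, NA_real_,
                             res$ratio_treatment / res$ratio_control)
  res
}

#' Median ratio change across genes
#'
#' Summary used to recover a cohort-level intron-retention change; excluded
#' genes are dropped.
#'
#' @param ratios Output of [splicing_ratio()].
#' @return Median `ratio_change` (numeric scalar).
#' @export
median_ratio_change <- function(ratios) {
  stats::median(ratios$ratio_change[!ratios$excluded], na.rm = TRUE)
}

#' Read a qPCR Ct table
#'
#' Tab-separated with header `sample`, `condition`, `target`, `replicate`,
#' `ct`. Undetected wells (no amplification) are encoded as empty/NA `ct`.
#'
#' @param path Input file.
#' @return `data.frame` of class `CtTable`.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "target", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  tab$ct <- as.numeric(tab$ct)
  if (any(!is.na(tab$ct) & tab$ct <= 0))
    stop("Ct values must be positive (undetected wells encoded as NA)")
  class(tab) <- c("CtTable", class(tab))
  tab
}

#' Relative transcript levels by the delta-delta-Ct method
#'
#' Technical replicates are averaged on the Ct scale per (sample, target);
#' each target is then normalized to the reference target within the same
#' sample (dCt = Ct_target - Ct_reference), condition means of dCt are
#' compared to the control condition (ddCt), and the relative level is
#' `2^(-ddCt)` — so the control condition maps to 1 by construction. The
#' standard deviation of the per-sample relative levels (biological
#' replicates) is reported.
#'
#' Targets with no detected Ct in a condition are reported with
#' `undetected = TRUE` and `NA` relative level.
#'
#' @param table A Ct table (see [read_ct_table()]).
#' @param reference_target Reference RNA target (default `"18S"`).
#' @param control_condition Control condition label (default `"L4440"`).
#' @return `data.frame` with one row per (target, condition): `delta_ct`,
#'   `delta_delta_ct`, `relative_level`, `sd_relative_level`, `n_samples`,
#'   `undetected`.
#' @export
delta_delta_ct <- function(table, reference_target = "18S",
                           control_condition = "L4440") {
  stopifnot(all(c("sample", "condition", "target", "ct") %in% names(table)))
  # technical replicates -> one Ct per (sample, target); all-NA stays NA
  agg <- stats::aggregate(ct ~ sample + condition + target, data = table,
                          FUN = function(x) mean(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  agg$ct[is.nan(agg$ct)] <- NA_real_
  ref <- agg[agg$target == reference_target, ]
  no_ref <- setdiff(unique(agg$sample), ref$sample[!is.na(ref$ct)])
  if (length(no_ref))
    stop("missing reference target '", reference_target, "' for sample(s): ",
         paste(no_ref, collapse = ", "))
  tgt <- agg[agg$target != reference_target, ]
  tgt$delta_ct <- tgt$ct - ref$ct[match(tgt$sample, ref$sample)]
  if (!control_condition %in% tgt$condition)
    stop("control condition '", control_condition, "' absent from Ct table")
  out <- do.call(rbind, lapply(split(tgt, tgt$target), function(d) {
    ctrl <- d$delta_ct[d$condition == control_condition]
    ctrl_mean <- mean(ctrl, na.rm = TRUE)
    do.call(rbind, lapply(split(d, d$condition), function(dc) {
      det <- !is.na(dc$delta_ct)
      ddct <- if (any(det) && is.finite(ctrl_mean))
        mean(dc$delta_ct[det]) - ctrl_mean else NA_real_
      per_sample <- 2^(-(dc$delta_ct[det] - ctrl_mean))
      data.frame(target = dc$target[1], condition = dc$condition[1],
                 n_samples = sum(det),
                 delta_ct = if (any(det)) mean(dc$delta_ct[det]) else NA_real_,
                 delta_delta_ct = ddct,
                 relative_level = if (is.na(ddct)) NA_real_ else 2^(-ddct),
                 sd_relative_level = if (sum(det) > 1) stats::sd(per_sample)
                                     else NA_real_,
                 undetected = !any(det),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Pre-mRNA/mRNA ratios from qPCR relative levels
#'
#' For each gene, the relative level of its pre-mRNA amplicon(s) (outron,
#' intron or intron-exon junction primers) is divided by the relative level of
#' its mRNA amplicon(s) (spliced exon-exon primers), per condition. A gene
#' whose pre-mRNA was never detected in a condition gets ratio 0 with
#' `undetected = TRUE` (the pattern of maternally deposited, already spliced
#' transcripts).
#'
#' @param table A Ct table (see [read_ct_table()]).
#' @param premrna_targets Named list: gene id -> character vector of pre-mRNA
#'   amplicon target names.
#' @param mrna_targets Named list: gene id -> mRNA amplicon target names.
#' @param reference_target,control_condition Passed to [delta_delta_ct()].
#' @return `data.frame` with `gene_id`, `condition`, `premrna_level`,
#'   `mrna_level`, `premrna_mrna_ratio`, `undetected`.
#' @export
premrna_mrna_qpcr <- function(table, premrna_targets, mrna_targets,
                              reference_target = "18S",
                              control_condition = "L4440") {
  genes <- union(names(premrna_targets), names(mrna_targets))
  miss <- genes[!(genes %in% names(premrna_targets) & genes %in% names(mrna_targets))]
  if (length(miss))
    stop("gene(s) absent from one target list: ", paste(miss, collapse = ", "))
  rel <- delta_delta_ct(table, reference_target, control_condition)
  lvl <- function(targets, cond) {
    r <- rel[rel$target %in% targets & rel$condition == cond, ]
    if (!nrow(r)) stop("no Ct rows for target(s): ", paste(targets, collapse = ", "))
    list(level = if (all(r$undetected)) NA_real_
                 else mean(r$relative_level, na.rm = TRUE),
         undetected = all(r$undetected))
  }
  conds <- unique(rel$condition)
  out <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(conds, function(cond) {
      p <- lvl(premrna_targets[[g]], cond)
      m <- lvl(mrna_targets[[g]], cond)
      data.frame(gene_id = g, condition = cond,
                 premrna_level = p$level, mrna_level = m$level,
                 premrna_mrna_ratio = if (p$undetected) 0
                   else p$level / m$level,
                 undetected = p$undetected,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
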