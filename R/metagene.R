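#' Anchored metagene profile of a coverage track
#'
#' Aligns genes at their TSS (or TES), lays out fixed windows from `-flank` to
#' `+flank` in transcript orientation (minus-strand genes are flipped), takes
#' the mean base signal per window per gene, and averages across genes. The
#' 95% confidence interval of the mean across genes is reported per window
#' (normal approximation, `1.96 * sd / sqrt(n)`); with a single contributing
#' gene the half-width is 0 (degenerate case). Windows extending past a
#' chromosome end are dropped for that gene, decrementing that window's `n`.
#'
#' The profile is anchored, not length-rescaled: windows beyond a short gene's
#' opposite end still read actual track signal.
#'
#' @param track A `CoverageTrack` (typically peak-masked and scaled upstream).
#' @param models A `GeneModels` object.
#' @param anchor `"tss"` or `"tes"`.
#' @param flank Bases either side of the anchor (default 1000).
#' @param window Window size in bases (default 50); must divide `flank` and be
#'   `<= flank`.
#' @param gene_set Optional character vector of gene ids to profile (defaults
#'   to all genes).
#' @param gene_set_label Label carried on the profile.
#' @return A `MetageneProfile`: `data.frame` with `window`, `offset` (of the
#'   window's 5' edge from the anchor, transcript orientation), `mean`,
#'   `ci_halfwidth`, `ci_low`, `ci_high`, `n_genes`; attributes `anchor`,
#'   `flank`, `window`, `gene_set_label`, `condition`.
#' @export
metagene_profile <- function(track, models, anchor = c("tss", "tes"),
                             flank = 1000, window = 50, gene_set = NULL,
                             gene_set_label = "all") {
  anchor <- match.arg(anchor)
  if (window > flank) stop("parameter error: window larger than flank")
  if (flank %% window != 0) stop("parameter error: flank not divisible by window")
  g <- models$genes
  if (!is.null(gene_set)) g <- g[names(g) %in% gene_set]
  if (!length(g)) stop("empty gene set")
  a <- if (anchor == "tss") tss_positions(models)[names(g)]
       else tes_positions(models)[names(g)]
  plus <- as.character(strand(g)) == "+"
  offsets <- seq(-flank, flank - window, by = window)
  nw <- length(offsets)
  lens <- chrom_lengths_of(track)
  chr <- as.character(seqnames(g))
  if (!all(chr %in% names(lens)))
    stop("gene(s) on chromosome(s) absent from track: ",
         paste(head(setdiff(chr, names(lens)), 3), collapse = ", "))

  vals <- matrix(NA_real_, nrow = length(g), ncol = nw)
  # genomic start of window j: plus -> a + off; minus -> a - off - window + 1
  for (j in seq_len(nw)) {
    st <- ifelse(plus, a + offsets[j], a - offsets[j] - window + 1L)
    en <- st + window - 1L
    ok <- st >= 1L & en <= lens[chr]
    if (any(ok)) {
      for (cc in unique(chr[ok])) {
        i <- ok & chr == cc
        vals[i, j] <- viewMeans(Views(track$cov[[cc]], IRanges(st[i], en[i])))
      }
    }
  }
  n <- colSums(!is.na(vals))
  mu <- ifelse(n > 0, colMeans(vals, na.rm = TRUE), NA_real_)
  sdv <- apply(vals, 2, stats::sd, na.rm = TRUE)
  ci <- ifelse(n > 1, 1.96 * sdv / sqrt(n), 0)
  prof <- data.frame(window = seq_len(nw), offset = offsets, mean = mu,
                     ci_halfwidth = ci, ci_low = mu - ci, ci_high = mu + ci,
                     n_genes = n)
  structure(prof, class = c("MetageneProfile", "data.frame"),
            anchor = anchor, flank = flank, window_size = window,
            gene_set_label = gene_set_label, condition = track$condition)
}

profile_geometry <- function(p)
  list(anchor = attr(p, "anchor"), flank = attr(p, "flank"),
       window = attr(p, "window_size"),
       gene_set_label = attr(p, "gene_set_label"))

#' TSS + TES metagene panel pair
#'
#' Convenience wrapper returning both anchored panels for one track and gene
#' set, the display unit of a metagene figure.
#'
#' @inheritParams metagene_profile
#' @return A `MetagenePair`: list with elements `tss` and `tes`.
#' @export
metagene_pair <- function(track, models, flank = 1000, window = 50,
                          gene_set = NULL, gene_set_label = "all") {
  structure(list(
    tss = metagene_profile(track, models, "tss", flank, window, gene_set,
                           gene_set_label),
    tes = metagene_profile(track, models, "tes", flank, window, gene_set,
                           gene_set_label)),
    class = "MetagenePair")
}

#' Combine replicate metagene profiles
#'
#' Replicates are combined as the mean of the replicate window means; the
#' reported interval half-width is the mean of the replicate half-widths.
#'
#' @param profiles List of `MetageneProfile`s with identical geometry.
#' @return A combined `MetageneProfile`.
#' @export
combine_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  g0 <- profile_geometry(profiles[[1]])
  for (p in profiles[-1])
    if (!identical(profile_geometry(p), g0))
      stop("mismatched geometry across replicate profiles")
  out <- profiles[[1]]
  out$mean <- rowMeans(sapply(profiles, `[[`, "mean"))
  out$ci_halfwidth <- rowMeans(sapply(profiles, `[[`, "ci_halfwidth"))
  out$ci_low <- out$mean - out$ci_halfwidth
  out$ci_high <- out$mean + out$ci_halfwidth
  out
}

#' 3'/5' travelling ratio of a metagene panel pair
#'
#' Mean of the TES-proximal gene-body windows (TES panel, offsets < 0) over
#' the mean of the TSS-proximal gene-body windows (TSS panel, offsets >= 0):
#' a scale-free summary of elongation-phase polymerase distribution. Values
#' above 1 indicate 3'-biased occupancy.
#'
#' @param pair A `MetagenePair`.
#' @return List with `ratio`, `ci_halfwidth` (delta-method propagation of the
#'   window CIs), `mean_5prime`, `mean_3prime`.
#' @export
travelling_ratio <- function(pair) {
  stopifnot(inherits(pair, "MetagenePair"))
  five <- pair$tss[pair$tss$offset >= 0, ]
  three <- pair$tes[pair$tes$offset < 0, ]
  m5 <- mean(five$mean); m3 <- mean(three$mean)
  # window means are correlated across genes; treating them as independent
  # gives a serviceable half-width for display
  se5 <- sqrt(sum(five$ci_halfwidth^2)) / nrow(five)
  se3 <- sqrt(sum(three$ci_halfwidth^2)) / nrow(three)
  r <- m3 / m5
  list(ratio = r,
       ci_halfwidth = abs(r) * sqrt((se5 / m5)^2 + (se3 / m3)^2),
       mean_5prime = m5, mean_3prime = m3)
}

#' Compare two metagene profiles or panel pairs
#'
#' For two single profiles of identical geometry: per-window difference
#' (`a - b`) with combined confidence half-width (quadrature). For two panel
#' pairs: per-window differences for both panels plus the 3'/5' travelling
#' ratio of each condition and their ratio of ratios.
#'
#' @param a,b `MetageneProfile`s or `MetagenePair`s of identical geometry.
#' @return For profiles: `data.frame` with `offset`, `difference`,
#'   `ci_halfwidth`. For pairs: list with `diff_tss`, `diff_tes`, `ratio_a`,
#'   `ratio_b` (each a [travelling_ratio()] result) and `ratio_of_ratios`.
#' @export
compare_profiles <- function(a, b) {
  if (inherits(a, "MetagenePair") && inherits(b, "MetagenePair")) {
    ra <- travelling_ratio(a); rb <- travelling_ratio(b)
    return(list(diff_tss = compare_profiles(a$tss, b$tss),
                diff_tes = compare_profiles(a$tes, b$tes),
                ratio_a = ra, ratio_b = rb,
                ratio_of_ratios = ra$ratio / rb$ratio))
  }
  stopifnot(inherits(a, "MetageneProfile"), inherits(b, "MetageneProfile"))
  if (!identical(profile_geometry(a), profile_geometry(b)))
    stop("mismatched geometry: profiles must share anchor, flank, window and gene set")
  data.frame(offset = a$offset,
             difference = a$mean - b$mean,
             ci_halfwidth = sqrt(a$ci_halfwidth^2 + b$ci_halfwidth^2))
}

#' Write a metagene profile as tab-separated text
#' @param profile A `MetageneProfile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot metagene panel pairs for one or more conditions
#'
#' TSS and TES panels side by side, mean signal with the 95% confidence
#' ribbon, one colour per condition.
#'
#' @param pairs Named list of `MetagenePair`s (names = condition labels).
#' @param title Plot title.
#' @return A `ggplot` object.
#' @export
plot_metagene <- function(pairs, title = "Metagene profile") {
  dat <- do.call(rbind, lapply(names(pairs), function(cond) {
    do.call(rbind, lapply(c("tss", "tes"), function(anch) {
      p <- as.data.frame(pairs[[cond]][[anch]])
      p$condition <- cond
      p$panel <- toupper(anch)
      p
    }))
  }))
  dat$panel <- factor(dat$panel, levels = c("TSS", "TES"))
  ggplot2::ggplot(dat, ggplot2::aes(x = offset, y = mean, colour = condition,
                                    fill = condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, nrow = 1) +
    ggplot2::labs(x = "offset from anchor (bp)", y = "mean scaled signal",
                  title = title) +
    ggplot2::theme_minimal()
}
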