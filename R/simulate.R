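#' Simulation configuration
#'
#' Parameters of the synthetic nascent-transcription genome: an
#' operon-containing toy genome whose genes carry cis-introns, outrons on a
#' trans-spliced fraction (default 0.70, the reported fraction of
#' trans-spliced mRNAs in *C. elegans*), condition-dependent intron retention,
#' and condition-dependent 3'-biased polymerase occupancy. The seed fully
#' determines every output.
#'
#' Coverage is generated per feature from closed-form expected means with
#' Poisson noise per `noise_tile`-bp tile: exon coverage is proportional to
#' the condition's transcription level, while intron and outron coverage is
#' proportional to the *control* level times the condition's intron-retention
#' factor (retained unspliced signal persists when transcription of mature
#' mRNA drops). Polymerase occupancy follows a per-gene linear gradient
#' calibrated so that the mean over the last kilobase of the gene body divided
#' by the mean over the first kilobase equals the condition's programmed 3'/5'
#' ratio.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes (class counts must not exceed it).
#' @param n_chromosomes Number of autosomes (an extra `chrX` is added when the
#'   chrX class count is positive).
#' @param gene_length_range Gene-body length range in bp (uniform draw).
#' @param exons_per_gene_range Range of exon counts per gene.
#' @param intron_length_range Intron length range in bp.
#' @param short_feature_prob Probability that an intron is replaced by a
#'   30-45 bp one (exercises the minimum-length filter).
#' @param fraction_trans_spliced Probability a gene is trans-spliced and
#'   carries an outron (default 0.70).
#' @param fraction_operon Probability a gene joins the previous gene's operon.
#' @param outron_length_range Outron length range in bp.
#' @param intergenic_gap Gap between consecutive gene bodies in bp (leaves
#'   room for outrons and metagene flanks).
#' @param read_length Nominal read length in bases.
#' @param rna_depth Expected exon coverage per unit transcription level.
#' @param chip_height Polymerase occupancy at the 5' gene body per unit level.
#' @param base_intron_fraction Intron coverage relative to exon coverage at
#'   retention factor 1.
#' @param noise_tile Poisson noise tile in bp.
#' @param class_counts Named gene counts per class (remaining genes are
#'   unclassified).
#' @param condition_labels Named character vector `c(control=, treatment=)`.
#' @param de_down_prob,de_up_prob Per-class probability of programmed down-
#'   or up-regulation under the treatment.
#' @param knockdown_down_factor,knockdown_up_factor Treatment/control
#'   transcription-level fold for programmed down/up genes.
#' @param intron_retention_factor Named `c(control=, treatment=)` retention
#'   factors (control 1 by definition).
#' @param polII_gradient Named `c(control=, treatment=)` 3'/5' occupancy
#'   ratios.
#' @param n_chip_replicates,n_rna_replicates Replicates per assay.
#' @param qpcr_bio,qpcr_tech Biological and technical qPCR replicates.
#' @param ct_sd Gaussian Ct jitter in cycles.
#' @param ct_offset Ct of a unit-abundance target.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 200,
                       n_chromosomes = 2,
                       gene_length_range = c(2500, 6000),
                       exons_per_gene_range = c(2, 7),
                       intron_length_range = c(60, 400),
                       short_feature_prob = 0.05,
                       fraction_trans_spliced = 0.70,
                       fraction_operon = 0.15,
                       outron_length_range = c(100, 400),
                       intergenic_gap = 2600,
                       read_length = 100,
                       rna_depth = 20,
                       chip_height = 10,
                       base_intron_fraction = 0.1,
                       noise_tile = 10,
                       class_counts = c(ubiquitous = 30, germline_enriched = 25,
                                        germline_specific = 20,
                                        soma_specific = 30,
                                        embryo_expressed = 40, chrX = 20,
                                        silent = 15),
                       condition_labels = c(control = "L4440",
                                            treatment = "knockdownRNAi"),
                       de_down_prob = c(ubiquitous = 0.25, soma_specific = 0.5,
                                        embryo_expressed = 0.6, chrX = 0.15),
                       de_up_prob = c(germline_enriched = 0.3,
                                      germline_specific = 0.3),
                       knockdown_down_factor = 0.25,
                       knockdown_up_factor = 2,
                       intron_retention_factor = c(control = 1, treatment = 3),
                       polII_gradient = c(control = 1.5, treatment = 0.8),
                       n_chip_replicates = 2,
                       n_rna_replicates = 1,
                       qpcr_bio = 2, qpcr_tech = 2,
                       ct_sd = 0.1, ct_offset = 20) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 1, sum(class_counts) <= n_genes,
            fraction_trans_spliced >= 0, fraction_trans_spliced <= 1,
            fraction_operon >= 0, fraction_operon <= 1,
            all(intron_retention_factor > 0), all(polII_gradient > 0),
            gene_length_range[1] >= 2500,
            all(c("control", "treatment") %in% names(condition_labels)))
  structure(cfg, class = "SimConfig")
}

# deterministic sub-seed (< 2^31) from the master seed and a purpose string
derive_seed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Simulate the toy genome and its ground truth
#'
#' Places non-overlapping genes on chromosomes, draws exon/intron structures,
#' assigns class labels, per-condition transcription levels, programmed
#' differential-expression status, trans-splicing flags and outrons, and
#' operon membership. Deterministic given the config seed.
#'
#' @param config A `SimConfig`.
#' @return A `NascentSim` list: `models` (`GeneModels`), `truth`
#'   (`data.frame`, one row per gene), `chrom_lengths` (named integer), and
#'   the `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(derive_seed(config$seed, "genome"))
  n <- config$n_genes
  ids <- sprintf("simg%04d", seq_len(n))

  classes <- rep("none", n)
  classes[seq_len(sum(config$class_counts))] <-
    rep(names(config$class_counts), config$class_counts)
  classes <- sample(classes)

  chroms <- paste0("chr", utils::as.roman(seq_len(config$n_chromosomes)))
  chrom <- sample(chroms, n, replace = TRUE)
  if (any(classes == "chrX")) chrom[classes == "chrX"] <- "chrX"

  strand_v <- sample(c("+", "-"), n, replace = TRUE)
  trans_spliced <- stats::runif(n) < config$fraction_trans_spliced
  outron_len <- ifelse(trans_spliced,
                       round(stats::runif(n, config$outron_length_range[1],
                                          config$outron_length_range[2])), 0L)

  level_control <- ifelse(classes == "silent", 0,
                          stats::rlnorm(n, meanlog = 0, sdlog = 0.4))
  de <- rep("none", n)
  class_prob <- function(v) {
    if (!length(v)) return(numeric(n))
    p <- unname(v[classes]); p[is.na(p)] <- 0
    p
  }
  pdown <- class_prob(config$de_down_prob)
  pup <- class_prob(config$de_up_prob)
  u <- stats::runif(n)
  de[level_control > 0 & u < pdown] <- "down"
  de[level_control > 0 & u >= pdown & u < pdown + pup] <- "up"
  level_treatment <- level_control *
    ifelse(de == "down", config$knockdown_down_factor,
           ifelse(de == "up", config$knockdown_up_factor, 1))

  # gene structures
  body_len <- round(stats::runif(n, config$gene_length_range[1],
                                 config$gene_length_range[2]))
  exon_list <- vector("list", n)
  for (i in seq_len(n)) {
    ne <- sample(seq(config$exons_per_gene_range[1],
                     config$exons_per_gene_range[2]), 1)
    il <- if (ne > 1)
      round(stats::runif(ne - 1, config$intron_length_range[1],
                         config$intron_length_range[2])) else integer(0)
    short <- stats::runif(length(il)) < config$short_feature_prob
    il[short] <- round(stats::runif(sum(short), 30, 45))
    # keep at least 60 bp of exon per exon: shrink introns if needed
    if (sum(il) > body_len[i] - 60 * ne)
      il <- pmax(30L, floor(il * (body_len[i] - 60 * ne) / sum(il)))
    ex_total <- body_len[i] - sum(il)
    # random exon lengths, each >= 30 bp, summing to the exonic total
    extra <- ex_total - 30L * ne
    props <- stats::runif(ne)
    alloc <- floor(extra * props / sum(props))
    el <- 30L + alloc
    el[1] <- el[1] + extra - sum(alloc)
    exon_list[[i]] <- list(exon = el, intron = il)
  }

  # placement, per chromosome in id order
  starts <- integer(n)
  chrom_lengths <- stats::setNames(integer(length(unique(chrom))), unique(chrom))
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    cursor <- 0L
    for (i in idx) {
      starts[i] <- cursor + config$intergenic_gap
      cursor <- starts[i] + body_len[i] - 1L
    }
    chrom_lengths[cc] <- cursor + config$intergenic_gap
  }
  ends <- starts + body_len - 1L

  # operons: a gene may join its left neighbour's operon on the same chromosome
  operon <- rep(NA_character_, n)
  op_n <- 0L
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    for (j in seq_along(idx)[-1]) {
      if (stats::runif(1) < config$fraction_operon) {
        i <- idx[j]; prev <- idx[j - 1]
        if (is.na(operon[prev])) {
          op_n <- op_n + 1L
          operon[prev] <- sprintf("simop%03d", op_n)
        }
        operon[i] <- operon[prev]
      }
    }
  }

  genes <- GRanges(chrom, IRanges(starts, ends), strand = strand_v)
  names(genes) <- ids
  plus <- strand_v == "+"
  mcols(genes)$gene_id <- ids
  mcols(genes)$tss <- ifelse(plus, starts, ends)
  mcols(genes)$tes <- ifelse(plus, ends, starts)
  mcols(genes)$operon_id <- operon
  mcols(genes)$biotype <- "protein_coding"

  exons <- GRangesList(lapply(seq_len(n), function(i) {
    el <- exon_list[[i]]$exon; il <- exon_list[[i]]$intron
    widths <- integer(length(el) + length(il))
    widths[seq_along(widths) %% 2 == 1] <- el
    if (length(il)) widths[seq_along(widths) %% 2 == 0] <- il
    s <- starts[i] + c(0L, cumsum(widths[-length(widths)]))
    fs <- s[seq_along(s) %% 2 == 1]
    GRanges(chrom[i], IRanges(fs, width = el), strand = strand_v[i])
  }))
  names(exons) <- ids
  introns <- psetdiff(granges(genes), exons)

  has_out <- trans_spliced
  og <- genes[has_out]
  op <- plus[has_out]
  ol <- outron_len[has_out]
  outrons <- GRanges(seqnames(og),
                     IRanges(ifelse(op, start(og) - ol, end(og) + 1L),
                             ifelse(op, start(og) - 1L, end(og) + ol)),
                     strand = strand(og))
  names(outrons) <- names(og)

  models <- new_gene_models(genes, exons, introns, outrons)
  truth <- data.frame(
    gene_id = ids, chrom = chrom, strand = strand_v, class = classes,
    body_length = body_len, n_exons = vapply(exon_list, function(x)
      length(x$exon), integer(1)),
    trans_spliced = trans_spliced, outron_length = outron_len,
    operon_id = operon, level_control = level_control,
    level_treatment = level_treatment, de_status = de,
    retention_control = unname(config$intron_retention_factor["control"]),
    retention_treatment = unname(config$intron_retention_factor["treatment"]),
    gradient_control = unname(config$polII_gradient["control"]),
    gradient_treatment = unname(config$polII_gradient["treatment"]),
    stringsAsFactors = FALSE)
  truth$expected_ratio_change <- ifelse(
    truth$level_treatment > 0,
    truth$retention_treatment * truth$level_control / truth$level_treatment,
    NA_real_)
  structure(list(models = models, truth = truth,
                 chrom_lengths = chrom_lengths, config = config),
            class = "NascentSim")
}

#' @export
print.NascentSim <- function(x, ...) {
  cat(sprintf("NascentSim: %d genes on %d chromosome(s), seed %d\n",
              nrow(x$truth), length(x$chrom_lengths), x$config$seed))
  invisible(x)
}

# per-base Poisson tile noise for a feature of width w at constant lambda
noisy_values <- function(w, lambda, tile) {
  nt <- ceiling(w / tile)
  counts <- stats::rpois(nt, lambda * tile) / tile
  rep(counts, each = tile)[seq_len(w)]
}

#' Simulate an RNA-seq coverage track
#'
#' Exon coverage is proportional to the condition's transcription level;
#' intron and outron coverage is proportional to the control level times the
#' condition's intron-retention factor. Poisson noise per tile.
#'
#' @param sim A `NascentSim` from [simulate_genome()].
#' @param condition `"control"` or `"treatment"`.
#' @param replicate Replicate index (enters the noise seed only).
#' @return A `CoverageTrack` (`assay = "rna"`).
#' @export
simulate_rna_coverage <- function(sim, condition = c("control", "treatment"),
                                  replicate = 1) {
  condition <- match.arg(condition)
  cfg <- sim$config
  set.seed(derive_seed(cfg$seed, paste("rna", condition, replicate)))
  level <- if (condition == "control") sim$truth$level_control
           else sim$truth$level_treatment
  pre_lambda <- cfg$rna_depth * cfg$base_intron_fraction *
    sim$truth$level_control * cfg$intron_retention_factor[[condition]]
  names(pre_lambda) <- sim$truth$gene_id
  exon_lambda <- cfg$rna_depth * level
  names(exon_lambda) <- sim$truth$gene_id

  flat <- function(grl) {
    u <- unlist(grl, use.names = FALSE)
    data.frame(chrom = as.character(seqnames(u)), start = start(u),
               end = end(u),
               gene = rep(names(grl), elementNROWS(grl)),
               stringsAsFactors = FALSE)
  }
  og <- sim$models$outrons
  feats <- rbind(
    cbind(flat(sim$models$exons), kind = "exon"),
    cbind(flat(sim$models$introns), kind = "pre"),
    if (length(og)) data.frame(chrom = as.character(seqnames(og)),
                               start = start(og), end = end(og),
                               gene = names(og), kind = "pre",
                               stringsAsFactors = FALSE))
  feats$lambda <- ifelse(feats$kind == "exon", exon_lambda[feats$gene],
                         pre_lambda[feats$gene])
  expressed <- stats::setNames(sim$truth$level_control > 0, sim$truth$gene_id)
  feats <- feats[expressed[feats$gene], ]

  vecs <- lapply(names(sim$chrom_lengths), function(cc) {
    v <- numeric(sim$chrom_lengths[[cc]])
    f <- feats[feats$chrom == cc, ]
    # deterministic order for the RNG stream
    f <- f[order(f$start), ]
    for (j in seq_len(nrow(f)))
      v[f$start[j]:f$end[j]] <-
        noisy_values(f$end[j] - f$start[j] + 1L, f$lambda[j], cfg$noise_tile)
    Rle(v)
  })
  names(vecs) <- names(sim$chrom_lengths)
  coverage_track(methods::as(vecs, "RleList"),
                 sample_label = sprintf("rna_%s_rep%d",
                                        cfg$condition_labels[[condition]],
                                        replicate),
                 condition = cfg$condition_labels[[condition]],
                 assay = "rna", read_length = cfg$read_length)
}

#' Simulate a polymerase ChIP coverage track and its peak calls
#'
#' Occupancy over each expressed gene body follows a linear gradient in
#' transcript orientation, calibrated per gene so the mean over the terminal
#' kilobase divided by the mean over the first kilobase equals the
#' condition's programmed 3'/5' ratio; amplitude scales with the control
#' transcription level (occupancy persists when mRNA output drops). Promoter-
#' proximal peak intervals are emitted per replicate with positional jitter.
#'
#' @param sim A `NascentSim`.
#' @param condition `"control"` or `"treatment"`.
#' @param replicate Replicate index.
#' @return List with `track` (`CoverageTrack`, `assay = "chip"`) and `peaks`
#'   (a `PeakSet`).
#' @export
simulate_polII <- function(sim, condition = c("control", "treatment"),
                           replicate = 1) {
  condition <- match.arg(condition)
  cfg <- sim$config
  set.seed(derive_seed(cfg$seed, paste("chip", condition, replicate)))
  g <- cfg$polII_gradient[[condition]]
  W <- 1000; m1 <- (W - 1) / 2
  gb <- sim$models$genes
  g_start <- start(gb); g_end <- end(gb)
  g_plus <- as.character(strand(gb)) == "+"
  g_tss <- mcols(gb)$tss
  peak_rows <- list()
  vecs <- lapply(names(sim$chrom_lengths), function(cc) {
    v <- numeric(sim$chrom_lengths[[cc]])
    idx <- which(sim$truth$chrom == cc & sim$truth$level_control > 0)
    idx <- idx[order(g_start[idx])]
    for (i in idx) {
      L <- g_end[i] - g_start[i] + 1L
      a <- cfg$chip_height * sim$truth$level_control[i]
      b <- a * (g - 1) / (L - W + m1 - g * m1)
      ramp <- a + b * seq(0, L - 1)
      if (!g_plus[i]) ramp <- rev(ramp)
      # Poisson tile noise around the ramp
      nt <- ceiling(L / cfg$noise_tile)
      pad <- nt * cfg$noise_tile - L
      tile_mean <- colMeans(matrix(c(ramp, rep(ramp[L], pad)),
                                   nrow = cfg$noise_tile))
      counts <- stats::rpois(nt, tile_mean * cfg$noise_tile) / cfg$noise_tile
      v[g_start[i]:g_end[i]] <- rep(counts, each = cfg$noise_tile)[seq_len(L)]
      # promoter-proximal peak, jittered per replicate
      j1 <- round(stats::rnorm(1, 0, 20)); j2 <- round(stats::rnorm(1, 0, 20))
      p <- if (g_plus[i]) c(g_tss[i] - 100 + j1, g_tss[i] + 200 + j2)
           else c(g_tss[i] - 200 + j1, g_tss[i] + 100 + j2)
      peak_rows[[length(peak_rows) + 1L]] <<-
        data.frame(chrom = cc, start = max(1, min(p)),
                   end = min(sim$chrom_lengths[[cc]], max(p)))
    }
    Rle(v)
  })
  names(vecs) <- names(sim$chrom_lengths)
  pk <- do.call(rbind, peak_rows)
  peaks <- peak_set(GRanges(pk$chrom, IRanges(pk$start, pk$end)),
                    condition = cfg$condition_labels[[condition]],
                    replicate = as.character(replicate),
                    source_format = "bed")
  track <- coverage_track(methods::as(vecs, "RleList"),
                          sample_label = sprintf("chip_%s_rep%d",
                                                 cfg$condition_labels[[condition]],
                                                 replicate),
                          condition = cfg$condition_labels[[condition]],
                          assay = "chip", read_length = cfg$read_length)
  list(track = track, peaks = peaks)
}

#' Membership role lists implied by the simulated classes
#'
#' Reconstructs the tissue-source role lists such that [build_catalog()] on
#' them reproduces the simulated class assignment. A few unclassified genes
#' are planted in the germline-enriched source *and* the spermatogenesis list
#' to exercise that subtraction.
#'
#' @param sim A `NascentSim`.
#' @return Named list of gene-id vectors (the roles of [build_catalog()]).
#' @export
truth_class_roles <- function(sim) {
  tr <- sim$truth
  of <- function(cls) tr$gene_id[tr$class == cls]
  sperm <- utils::head(tr$gene_id[tr$class == "none"], 3)
  list(germline = c(of("germline_specific"), of("ubiquitous")),
       neuronal = of("ubiquitous"),
       muscle = of("ubiquitous"),
       gut = of("ubiquitous"),
       somatic_any = c(of("soma_specific"), of("ubiquitous")),
       germline_enriched_src = c(of("germline_enriched"), sperm),
       strict_maternal = of("germline_specific"),
       strict_embryonic = of("embryo_expressed"),
       chrX_all = of("chrX"),
       silent_src = of("silent"),
       sperm_genes = sperm)
}

#' Simulate a qPCR Ct table with known relative levels
#'
#' Picks trans-spliced embryonically expressed genes (pre-mRNA amplicons
#' detectable) and maternal germline-specific genes (pre-mRNA absent: those
#' transcripts are deposited already spliced), plus the 18S reference. Each
#' biological sample carries its own plate offset; Ct = offset -
#' log2(abundance) + Gaussian jitter.
#'
#' @param sim A `NascentSim`.
#' @return List with `table` (`CtTable` rows), `premrna_targets`,
#'   `mrna_targets` (named lists for [premrna_mrna_qpcr()]) and `expected`
#'   (`data.frame` of true relative mRNA levels per gene and condition).
#' @export
simulate_ct_table <- function(sim) {
  cfg <- sim$config
  set.seed(derive_seed(cfg$seed, "qpcr"))
  tr <- sim$truth
  emb <- utils::head(tr$gene_id[tr$class == "embryo_expressed" &
                                  tr$trans_spliced & tr$level_control > 0], 4)
  mat <- utils::head(tr$gene_id[tr$class == "germline_specific" &
                                  tr$level_control > 0], 3)
  genes <- c(emb, mat)
  if (!length(genes)) stop("no suitable qPCR genes in this simulation")
  maternal <- genes %in% mat
  rows <- list()
  for (cond in c("control", "treatment")) {
    lab <- cfg$condition_labels[[cond]]
    lvl <- if (cond == "control") tr$level_control else tr$level_treatment
    ret <- cfg$intron_retention_factor[[cond]]
    for (s in seq_len(cfg$qpcr_bio)) {
      sample_id <- sprintf("%s_bio%d", lab, s)
      scale <- stats::rlnorm(1, 0, 0.3)  # plate/input offset, cancels in dCt
      add <- function(target, abundance) {
        ct <- if (is.na(abundance) || abundance <= 0) rep(NA_real_, cfg$qpcr_tech)
              else cfg$ct_offset - log2(abundance * scale) +
                stats::rnorm(cfg$qpcr_tech, 0, cfg$ct_sd)
        rows[[length(rows) + 1L]] <<- data.frame(
          sample = sample_id, condition = lab, target = target,
          replicate = seq_len(cfg$qpcr_tech), ct = ct,
          stringsAsFactors = FALSE)
      }
      add("18S", 1)
      for (gi in seq_along(genes)) {
        gid <- genes[gi]
        i <- match(gid, tr$gene_id)
        add(paste0(gid, "_exon"), lvl[i])
        pre <- if (maternal[gi]) NA_real_
               else cfg$base_intron_fraction * tr$level_control[i] * ret
        add(paste0(gid, "_pre"), pre)
      }
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("CtTable", class(tab))
  expected <- do.call(rbind, lapply(genes, function(gid) {
    i <- match(gid, tr$gene_id)
    data.frame(gene_id = gid,
               condition = unname(cfg$condition_labels),
               true_relative_mrna = c(1, tr$level_treatment[i] /
                                        tr$level_control[i]),
               stringsAsFactors = FALSE)
  }))
  list(table = tab,
       premrna_targets = stats::setNames(as.list(paste0(genes, "_pre")), genes),
       mrna_targets = stats::setNames(as.list(paste0(genes, "_exon")), genes),
       expected = expected)
}

#' Differential-expression table implied by the simulated truth
#'
#' Synthesized, not estimated: log2 fold changes derive from the programmed
#' per-condition transcription levels (with mild jitter) and q-values are
#' 0.001 for programmed DE genes and 0.5 otherwise. Only expressed genes
#' (the analysis universe with sufficient read representation) appear.
#'
#' @param sim A `NascentSim`.
#' @return `data.frame` with `gene_id`, `log2fc`, `q`.
#' @export
simulate_de_table <- function(sim) {
  set.seed(derive_seed(sim$config$seed, "de"))
  tr <- sim$truth[sim$truth$level_control > 0, ]
  data.frame(gene_id = tr$gene_id,
             log2fc = log2(tr$level_treatment / tr$level_control) +
               stats::rnorm(nrow(tr), 0, 0.05),
             q = ifelse(tr$de_status == "none", 0.5, 0.001),
             stringsAsFactors = FALSE)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 10)

write_manifest <- function(kv, path) {
  writeLines(sprintf("%s=%s", names(kv), vapply(kv, as.character, character(1))),
             path)
  invisible(path)
}

#' Read a fixture-bundle manifest
#' @param path `manifest.txt` inside a bundle.
#' @return Named list of values (chromosome lengths parsed to a named
#'   integer vector under `chrom_lengths`).
#' @export
read_manifest <- function(path) {
  ln <- readLines(path)
  kv <- strsplit(ln[nzchar(ln)], "=", fixed = TRUE)
  out <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                         vapply(kv, `[`, character(1), 1))
  if (!is.null(out$chrom_lengths)) {
    parts <- strsplit(strsplit(out$chrom_lengths, ",")[[1]], ":")
    out$chrom_lengths <- stats::setNames(
      as.integer(vapply(parts, `[`, character(1), 2)),
      vapply(parts, `[`, character(1), 1))
  }
  for (f in c("seed", "n_genes", "read_length"))
    if (!is.null(out[[f]])) out[[f]] <- as.numeric(out[[f]])
  out
}

#' Write a complete synthetic fixture bundle
#'
#' Emits, under `dir`: the annotation (`annotation.gtf`), the nascent-TSS
#' override BED (`tss_override.bed`, outron anchors of trans-spliced genes),
#' bedGraph coverage per assay/condition/replicate, peak BED files per ChIP
#' replicate, the DE table, one membership list per catalog role under
#' `classes/`, the qPCR Ct table, the per-gene ground truth (`truth.tsv`) and
#' a flat `manifest.txt` recording the seed and key parameters. Byte-identical
#' across runs with the same config.
#'
#' @param config A `SimConfig`.
#' @param dir Output directory.
#' @param overwrite Overwrite an existing bundle (default `FALSE`).
#' @return The `NascentSim` object, invisibly.
#' @export
emit_fixture_bundle <- function(config, dir, overwrite = FALSE) {
  if (file.exists(file.path(dir, "manifest.txt")) && !overwrite)
    stop("bundle already present at ", dir, " (use overwrite = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "classes"), showWarnings = FALSE)
  sim <- simulate_genome(config)
  write_gtf(sim$models, file.path(dir, "annotation.gtf"))

  o <- sim$models$outrons
  if (length(o)) {
    g <- sim$models$genes[names(o)]
    plus <- as.character(strand(g)) == "+"
    pos <- ifelse(plus, start(o), end(o))  # nascent TSS, 1-based
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", as.character(seqnames(o)),
                       pos - 1L, pos, names(o), as.character(strand(o))),
               file.path(dir, "tss_override.bed"))
  } else writeLines(character(0), file.path(dir, "tss_override.bed"))

  for (cond in c("control", "treatment")) {
    lab <- config$condition_labels[[cond]]
    for (r in seq_len(config$n_rna_replicates)) {
      tr <- simulate_rna_coverage(sim, cond, r)
      write_bedgraph(tr, file.path(dir, sprintf("rna_%s_rep%d.bedgraph", lab, r)))
    }
    for (r in seq_len(config$n_chip_replicates)) {
      ch <- simulate_polII(sim, cond, r)
      write_bedgraph(ch$track,
                     file.path(dir, sprintf("chip_%s_rep%d.bedgraph", lab, r)))
      pk <- ch$peaks$intervals
      writeLines(sprintf("%s\t%d\t%d\tpeak%d\t0\t.",
                         as.character(seqnames(pk)), start(pk) - 1L, end(pk),
                         seq_along(pk)),
                 file.path(dir, sprintf("peaks_%s_rep%d.bed", lab, r)))
    }
  }

  de <- simulate_de_table(sim)
  de$log2fc <- fmt_num(de$log2fc)
  utils::write.table(de, file.path(dir, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  roles <- truth_class_roles(sim)
  for (role in names(roles))
    writeLines(roles[[role]], file.path(dir, "classes", paste0(role, ".txt")))

  q <- simulate_ct_table(sim)
  qt <- q$table
  qt$ct <- ifelse(is.na(qt$ct), "", fmt_num(qt$ct))
  utils::write.table(qt, file.path(dir, "ct_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  tt <- sim$truth
  for (cc in names(tt))
    if (is.numeric(tt[[cc]]) && !is.integer(tt[[cc]])) tt[[cc]] <- fmt_num(tt[[cc]])
  utils::write.table(tt, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_manifest(list(
    seed = config$seed, n_genes = config$n_genes,
    read_length = config$read_length,
    control_label = config$condition_labels[["control"]],
    treatment_label = config$condition_labels[["treatment"]],
    n_rna_replicates = config$n_rna_replicates,
    n_chip_replicates = config$n_chip_replicates,
    intron_retention_treatment = config$intron_retention_factor[["treatment"]],
    gradient_control = config$polII_gradient[["control"]],
    gradient_treatment = config$polII_gradient[["treatment"]],
    chrom_lengths = paste(sprintf("%s:%d", names(sim$chrom_lengths),
                                  sim$chrom_lengths), collapse = ",")),
    file.path(dir, "manifest.txt"))
  invisible(sim)
}
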