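#' Pipeline configuration
#'
#' Collects the input paths and the analysis parameters shared by all stages.
#' Any field can also be supplied through a flat YAML config file
#' ([read_pipeline_config()]); unknown fields are rejected.
#'
#' @param annotation Annotation file (GFF3/GTF).
#' @param tss_override Optional nascent-TSS BED (outron anchors).
#' @param rna_tracks Named list: condition label -> character vector of RNA
#'   bedGraph paths (replicates).
#' @param chip_tracks Named list: condition label -> ChIP bedGraph paths.
#' @param peak_files Named list: condition label -> peak BED/broadPeak paths.
#' @param de_table DE table path.
#' @param de_layout `"standard"` or `"cuffdiff"`.
#' @param class_dir Directory of role membership lists (`<role>.txt`).
#' @param ct_table qPCR Ct table path.
#' @param control_condition,treatment_condition Condition labels; the control
#'   default follows the empty-vector RNAi convention (`"L4440"`).
#' @param chrom_lengths Named integer vector of chromosome lengths (read from
#'   a bundle manifest when loading one).
#' @param min_feature_length Minimum exon/intron length in bp (default 50).
#' @param flank,window Metagene geometry in bp (defaults 1000 / 50).
#' @param chip_target_reads,rna_target_reads Scaling targets in
#'   read-equivalents (defaults 2e6 / 1e7).
#' @param min_fold,max_q DE selection thresholds (defaults 2 / 0.05).
#' @param pseudocount Log2 offset for coverage tables (default 1).
#' @param read_length Nominal read length in bases (default 100).
#' @param out_dir Output directory.
#' @param seed Seed for the `simulate` stage.
#' @return A validated `PipelineConfig` list.
#' @export
pipeline_config <- function(annotation = NULL, tss_override = NULL,
                            rna_tracks = list(), chip_tracks = list(),
                            peak_files = list(), de_table = NULL,
                            de_layout = "standard", class_dir = NULL,
                            ct_table = NULL,
                            control_condition = "L4440",
                            treatment_condition = "knockdownRNAi",
                            chrom_lengths = NULL,
                            min_feature_length = 50, flank = 1000,
                            window = 50, chip_target_reads = 2e6,
                            rna_target_reads = 1e7, min_fold = 2,
                            max_q = 0.05, pseudocount = 1, read_length = 100,
                            out_dir = "nascentr_out", seed = 1) {
  cfg <- as.list(environment())
  validate_pipeline_config(cfg)
  structure(cfg, class = "PipelineConfig")
}

validate_pipeline_config <- function(cfg) {
  num <- c("min_feature_length", "flank", "window", "chip_target_reads",
           "rna_target_reads", "min_fold", "max_q", "pseudocount",
           "read_length")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0)
      stop("config error: field '", f, "' must be a positive number")
  if (cfg$flank %% cfg$window != 0)
    stop("config error: field 'window' must divide 'flank'")
  if (cfg$min_fold <= 1)
    stop("config error: field 'min_fold' must exceed 1")
  invisible(cfg)
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error. `...` overrides (e.g. from command-line flags) take precedence over
#' the file.
#'
#' @param path YAML file.
#' @param ... Named overrides.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  vals <- yaml::read_yaml(path)
  over <- list(...)
  vals[names(over)] <- over
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("config error: unknown field '", bad[1], "'")
  if (!is.null(vals$chrom_lengths))
    vals$chrom_lengths <- unlist(vals$chrom_lengths)
  do.call(pipeline_config, vals)
}

#' Build a pipeline configuration for a simulated fixture bundle
#'
#' Maps the files of an [emit_fixture_bundle()] directory onto a
#' `PipelineConfig`, taking condition labels and chromosome lengths from the
#' bundle manifest.
#'
#' @param dir Bundle directory.
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `PipelineConfig`.
#' @export
bundle_config <- function(dir, ...) {
  man <- read_manifest(file.path(dir, "manifest.txt"))
  ctrl <- man$control_label; trt <- man$treatment_label
  track_paths <- function(prefix, lab, n)
    file.path(dir, sprintf("%s_%s_rep%d.bedgraph", prefix, lab, seq_len(n)))
  args <- list(
    annotation = file.path(dir, "annotation.gtf"),
    tss_override = file.path(dir, "tss_override.bed"),
    rna_tracks = stats::setNames(
      list(track_paths("rna", ctrl, man$n_rna_replicates),
           track_paths("rna", trt, man$n_rna_replicates)), c(ctrl, trt)),
    chip_tracks = stats::setNames(
      list(track_paths("chip", ctrl, man$n_chip_replicates),
           track_paths("chip", trt, man$n_chip_replicates)), c(ctrl, trt)),
    peak_files = stats::setNames(
      list(file.path(dir, sprintf("peaks_%s_rep%d.bed", ctrl,
                                  seq_len(man$n_chip_replicates))),
           file.path(dir, sprintf("peaks_%s_rep%d.bed", trt,
                                  seq_len(man$n_chip_replicates)))),
      c(ctrl, trt)),
    de_table = file.path(dir, "de_table.tsv"),
    class_dir = file.path(dir, "classes"),
    ct_table = file.path(dir, "ct_table.tsv"),
    control_condition = ctrl, treatment_condition = trt,
    chrom_lengths = man$chrom_lengths,
    read_length = man$read_length,
    seed = man$seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

need_input <- function(paths, what) {
  paths <- unlist(paths)
  if (!length(paths)) stop("input error: no ", what, " configured")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input error: missing ", what, ": ", missing[1])
  invisible(paths)
}

log_line <- function(state, fmt, ...) {
  state$log <- c(state$log, sprintf(fmt, ...))
  state
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages behind one entry point. Stage outputs (tab-
#' separated tables, gene lists, figures as PDF plus the tabular data behind
#' them) are written under `config$out_dir`; a `pipeline_log.txt` records
#' parameters, input checksums and the row counts entering and leaving each
#' filter.
#'
#' Subcommands: `features` (feature catalog + counts), `splicing` (per-gene
#' coverage tables and pre-mRNA/mRNA ratio changes), `metagene` (TSS/TES
#' panels per gene class and travelling ratios), `binding` (bound-gene lists),
#' `enrich` (DE selection + class enrichment), `qpcr` (delta-delta-Ct tables),
#' `simulate` (write a fixture bundle into `out_dir`), `all` (everything
#' applicable).
#'
#' @param config A `PipelineConfig`.
#' @param subcommand One of `features`, `splicing`, `metagene`, `binding`,
#'   `enrich`, `qpcr`, `simulate`, `all`.
#' @param overwrite Allow writing into an existing output directory.
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config,
                         subcommand = c("all", "features", "splicing",
                                        "metagene", "binding", "enrich",
                                        "qpcr", "simulate"),
                         overwrite = TRUE) {
  subcommand <- match.arg(subcommand)
  validate_pipeline_config(config)
  out <- config$out_dir
  if (dir.exists(out) && !overwrite && length(list.files(out)))
    stop("input error: output directory not empty: ", out)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  state <- list(log = character(0), results = list())
  state <- log_line(state, "nascentr pipeline: subcommand=%s", subcommand)
  for (f in c("min_feature_length", "flank", "window", "chip_target_reads",
              "rna_target_reads", "min_fold", "max_q", "pseudocount",
              "read_length"))
    state <- log_line(state, "param %s=%s", f, format(config[[f]]))

  if (subcommand == "simulate") {
    sim <- emit_fixture_bundle(sim_config(seed = config$seed), out,
                               overwrite = overwrite)
    state <- log_line(state, "simulate: %d genes, seed %d", nrow(sim$truth),
                      config$seed)
    writeLines(state$log, file.path(out, "pipeline_log.txt"))
    return(invisible(list(sim = sim)))
  }

  checksum <- function(p) unname(tools::md5sum(p))
  stages <- if (subcommand == "all")
    c("features", "splicing", "metagene", "binding", "enrich", "qpcr")
  else subcommand

  need_input(config$annotation, "annotation")
  state <- log_line(state, "input %s md5=%s", config$annotation,
                    checksum(config$annotation))
  models <- parse_annotation(config$annotation,
                             tss_override = config$tss_override)
  state <- log_line(state, "annotation: %d genes, %d with outrons",
                    length(models), length(models$outrons))
  catalog <- derive_features(models, config$min_feature_length)
  state <- log_line(state,
                    "features: retained %d exons, %d introns (min length %d)",
                    catalog$n_exons, catalog$n_introns, catalog$min_length)

  load_cond_tracks <- function(paths, assay, cond) {
    lapply(seq_along(paths), function(i)
      load_track(paths[i], read_length = config$read_length,
                 chrom_lengths = config$chrom_lengths,
                 condition = cond, assay = assay))
  }

  if ("features" %in% stages) {
    write_feature_bed(catalog, file.path(out, "features.bed"))
    write_feature_summary(catalog, file.path(out, "feature_counts.tsv"))
    state$results$catalog <- catalog
  }

  if ("splicing" %in% stages) {
    need_input(config$rna_tracks, "RNA tracks")
    ctrl <- config$control_condition; trt <- config$treatment_condition
    tabs <- lapply(stats::setNames(c(ctrl, trt), c(ctrl, trt)), function(cond) {
      trks <- load_cond_tracks(config$rna_tracks[[cond]], "rna", cond)
      trks <- lapply(trks, mask_and_scale, mask_regions = GRanges(),
                     target_reads = config$rna_target_reads)
      tt <- lapply(trks, gene_feature_table, catalog = catalog,
                   models = models, pseudocount = config$pseudocount)
      # replicate tracks averaged on the coverage-mean scale
      avg <- tt[[1]]
      if (length(tt) > 1)
        for (cc in c("mean_exon_cov", "mean_intron_cov", "mean_outron_cov"))
          avg[[cc]] <- rowMeans(sapply(tt, `[[`, cc))
      avg
    })
    for (cond in names(tabs))
      utils::write.table(tabs[[cond]],
                         file.path(out, sprintf("feature_coverage_%s.tsv", cond)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    ratios <- splicing_ratio(tabs[[trt]], tabs[[ctrl]], numerator = "intron")
    utils::write.table(ratios, file.path(out, "splicing_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state <- log_line(state,
                      "splicing: %d genes, %d excluded, median ratio_change %.3f",
                      nrow(ratios), sum(ratios$excluded),
                      median_ratio_change(ratios))
    state$results$feature_tables <- tabs
    state$results$splicing <- ratios
  }

  if ("binding" %in% stages || "metagene" %in% stages) {
    need_input(config$peak_files, "peak files")
    peaksets <- lapply(names(config$peak_files), function(cond)
      lapply(seq_along(config$peak_files[[cond]]), function(i)
        read_peaks(config$peak_files[[cond]][i], condition = cond,
                   replicate = as.character(i))))
    names(peaksets) <- names(config$peak_files)
  }

  if ("binding" %in% stages) {
    bound <- lapply(peaksets, function(ps)
      call_bound_genes(ps[[1]], ps[[2]], models))
    for (cond in names(bound)) {
      write_gene_list(bound[[cond]],
                      file.path(out, sprintf("bound_genes_%s.txt", cond)))
      state <- log_line(state, "binding: %d genes bound in %s",
                        length(bound[[cond]]), cond)
    }
    state$results$bound <- bound
  }

  classes <- NULL
  if (("enrich" %in% stages || "metagene" %in% stages) &&
      !is.null(config$class_dir)) {
    role_files <- list.files(config$class_dir, pattern = "\\.txt$",
                             full.names = TRUE)
    roles <- lapply(role_files, read_gene_list)
    names(roles) <- sub("\\.txt$", "", basename(role_files))
    classes <- build_catalog(roles)
  }

  if ("metagene" %in% stages) {
    need_input(config$chip_tracks, "ChIP tracks")
    mask <- reduce(unlist(GRangesList(unlist(lapply(peaksets, function(ps)
      lapply(ps, `[[`, "intervals"))))))
    state <- log_line(state, "metagene: peak mask of %d regions", length(mask))
    scaled <- lapply(stats::setNames(nm = names(config$chip_tracks)), function(cond) {
      trks <- load_cond_tracks(config$chip_tracks[[cond]], "chip", cond)
      lapply(trks, mask_and_scale, mask_regions = mask,
             target_reads = config$chip_target_reads)
    })
    combined_pair <- function(trks, gene_set = NULL, label = "all") {
      reps <- lapply(trks, metagene_pair, models = models,
                     flank = config$flank, window = config$window,
                     gene_set = gene_set, gene_set_label = label)
      structure(list(tss = combine_profiles(lapply(reps, `[[`, "tss")),
                     tes = combine_profiles(lapply(reps, `[[`, "tes"))),
                class = "MetagenePair")
    }
    pairs <- lapply(scaled, combined_pair)
    if (!is.null(classes)) {
      for (cls in names(classes)) {
        ids <- intersect(classes[[cls]], gene_ids(models))
        if (length(ids) < 2) next
        for (cond in names(scaled)) {
          cp <- combined_pair(scaled[[cond]], gene_set = ids, label = cls)
          write_profile(cp$tss, file.path(
            out, sprintf("metagene_tss_%s_%s.tsv", cls, cond)))
          write_profile(cp$tes, file.path(
            out, sprintf("metagene_tes_%s_%s.tsv", cls, cond)))
        }
      }
    }
    for (cond in names(pairs)) {
      write_profile(pairs[[cond]]$tss,
                    file.path(out, sprintf("metagene_tss_%s.tsv", cond)))
      write_profile(pairs[[cond]]$tes,
                    file.path(out, sprintf("metagene_tes_%s.tsv", cond)))
      tr <- travelling_ratio(pairs[[cond]])
      state <- log_line(state, "metagene: %s 3'/5' ratio %.3f (ci %.3f)",
                        cond, tr$ratio, tr$ci_halfwidth)
    }
    grDevices::pdf(file.path(out, "metagene_all_genes.pdf"), width = 8,
                   height = 4)
    print(plot_metagene(pairs, title = "Pol II metagene, all genes"))
    grDevices::dev.off()
    cmp <- compare_profiles(pairs[[config$treatment_condition]],
                            pairs[[config$control_condition]])
    state <- log_line(state, "metagene: ratio of 3'/5' ratios %.3f",
                      cmp$ratio_of_ratios)
    state$results$metagene <- pairs
    state$results$metagene_comparison <- cmp
  }

  if ("enrich" %in% stages) {
    need_input(config$de_table, "DE table")
    de <- read_de_table(config$de_table, layout = config$de_layout)
    sel <- select_de_genes(de, config$min_fold, config$max_q)
    state <- log_line(state, "enrich: %d rows -> %d down, %d up (fold>%g, q<=%g)",
                      nrow(de), length(sel$down), length(sel$up),
                      config$min_fold, config$max_q)
    universe <- de$gene_id
    if (!is.null(classes)) {
      for (dirn in c("down", "up")) {
        rep_tab <- enrichment_report(sel[[dirn]], universe, classes)
        utils::write.table(rep_tab,
                           file.path(out, sprintf("enrichment_%s.tsv", dirn)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        grDevices::pdf(file.path(out, sprintf("enrichment_%s.pdf", dirn)),
                       width = 6, height = 4)
        print(plot_enrichment(rep_tab,
                              title = sprintf("%s-regulated genes", dirn)))
        grDevices::dev.off()
        state$results[[paste0("enrichment_", dirn)]] <- rep_tab
      }
    }
    write_gene_list(sel$down, file.path(out, "de_down.txt"))
    write_gene_list(sel$up, file.path(out, "de_up.txt"))
    state$results$de_selection <- sel
  }

  if ("qpcr" %in% stages && !is.null(config$ct_table) &&
      file.exists(config$ct_table)) {
    ct <- read_ct_table(config$ct_table)
    rel <- delta_delta_ct(ct, control_condition = config$control_condition)
    utils::write.table(rel, file.path(out, "qpcr_relative_levels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state <- log_line(state, "qpcr: %d target/condition levels", nrow(rel))
    state$results$qpcr <- rel
  }

  writeLines(state$log, file.path(out, "pipeline_log.txt"))
  invisible(state$results)
}
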