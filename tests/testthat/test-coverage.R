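test_that("read intervals stack into per-base coverage", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "reads.bed")
  writeLines(c("chr1\t0\t10\tr1", "chr1\t5\t15\tr2"), bed)
  tr <- load_track(bed, format = "bed_reads",
                   chrom_lengths = c(chr1 = 20L))
  expect_equal(as.numeric(tr$cov$chr1),
               c(rep(1, 5), rep(2, 5), rep(1, 5), rep(0, 5)))
})

test_that("empty input yields an all-zero track and bad values error", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.bedgraph")
  file.create(empty)
  tr <- load_track(empty, format = "bedgraph",
                   chrom_lengths = c(chr1 = 100L))
  expect_equal(sum(as.numeric(tr$cov$chr1)), 0)
  expect_equal(length(tr$cov$chr1), 100)

  neg <- file.path(dir, "neg.bedgraph")
  writeLines("chr1\t0\t10\t-1", neg)
  expect_error(load_track(neg, format = "bedgraph"), "negative")

  unk <- file.path(dir, "unk.bedgraph")
  writeLines(c("chr1\t0\t10\t2", "chrZ\t0\t10\t2"), unk)
  expect_warning(load_track(unk, format = "bedgraph",
                            chrom_lengths = c(chr1 = 100L)),
                 "1 record")
})

test_that("mean feature coverage is length-weighted and split-invariant", {
  tr <- flat_track(3, len = 200)
  expect_equal(mean_feature_coverage(tr, GRanges("chr1", IRanges(1, 100))), 3)

  # piecewise 2 then 4 over [1,100]
  tr2 <- coverage_track(list(chr1 = Rle(c(2, 4), c(50, 50))))
  gr <- GRanges("chr1", IRanges(1, 100))
  expect_equal(mean_feature_coverage(tr2, gr), 3)
  # splitting the interval changes nothing
  split2 <- GRanges("chr1", IRanges(c(1, 31), c(30, 100)))
  expect_equal(mean_feature_coverage(tr2, split2),
               mean_feature_coverage(tr2, gr))

  # features of length 10 (cov 10) and 90 (cov 0) -> pooled mean 1
  tr3 <- coverage_track(list(chr1 = Rle(c(10, 0), c(10, 90))))
  gr3 <- GRanges("chr1", IRanges(c(1, 11), c(10, 100)))
  expect_equal(mean_feature_coverage(tr3, gr3), 1)

  expect_error(mean_feature_coverage(tr3, GRanges("chrZ", IRanges(1, 10))),
               "unknown chromosome")
  expect_error(mean_feature_coverage(tr3, GRanges("chr1", IRanges(90, 200))),
               "bounds")
})

test_that("mean feature coverage matches a brute-force per-base oracle", {
  set.seed(11)
  for (rep in 1:5) {
    v <- rpois(5000, 2) * runif(5000)
    tr <- coverage_track(list(chr1 = Rle(v)))
    s <- sort(sample(4900, 4))
    gr <- GRanges("chr1", IRanges(s, s + sample(50, 4)))
    gr <- reduce(gr)
    base_mask <- unlist(lapply(seq_along(gr), function(i)
      start(gr)[i]:end(gr)[i]))
    expect_equal(mean_feature_coverage(tr, gr), mean(v[base_mask]))
  }
})

test_that("peak-masked global scaling hits the target read total exactly", {
  # uniform coverage 2 over 1000 bases, read length 10 -> 200 read-equivalents
  tr <- flat_track(2, len = 1000, read_length = 10, assay = "chip")
  expect_equal(track_read_total(tr), 200)

  sc <- mask_and_scale(tr, target_reads = 50)
  expect_equal(track_read_total(sc), 50, tolerance = 1e-9)
  expect_equal(as.numeric(sc$cov$chr1[1]), 0.5)

  # mask covering half the track: factor computed from the unmasked half
  mask <- GRanges("chr1", IRanges(1, 500))
  sm <- mask_and_scale(tr, mask_regions = mask, target_reads = 100)
  expect_equal(track_read_total(sm), 100, tolerance = 1e-9)
  expect_equal(as.numeric(sm$cov$chr1[700]), 2)  # 100/(1000/10 * 2/2)=1 -> x1... value checked below
  # unmasked half holds 100 read-equivalents pre-scaling -> factor 1
  expect_equal(as.numeric(sm$cov$chr1[1]), 2)    # masked values scaled too

  # composition: scaling to T then U equals scaling once to U
  s1 <- mask_and_scale(mask_and_scale(tr, target_reads = 70),
                       target_reads = 30)
  s2 <- mask_and_scale(tr, target_reads = 30)
  expect_equal(as.numeric(s1$cov$chr1), as.numeric(s2$cov$chr1))

  # zero unmasked signal is undefined
  z <- flat_track(0, len = 100)
  expect_error(mask_and_scale(z, target_reads = 10), "zero unmasked")

  # assay defaults: 2e6 for ChIP, 1e7 for RNA
  expect_equal(track_read_total(mask_and_scale(tr)), 2e6)
  trr <- flat_track(2, len = 1000, read_length = 10, assay = "rna")
  expect_equal(track_read_total(mask_and_scale(trr)), 1e7)
})

test_that("scaling conserves the target on rough simulated tracks", {
  sim <- shared_sim()
  ch <- suppressMessages(simulate_polII(sim, "control", 1))
  sc <- mask_and_scale(ch$track, mask_regions = ch$peaks$intervals)
  expect_equal(track_read_total(sc), 2e6, tolerance = 1e-6)
})

test_that("per-gene feature coverage table reports pooled means and log2", {
  m <- toy_models(c(101, 201), c(160, 300))  # exon 60+100, intron 40... use min_length 1
  catal <- derive_features(m, min_length = 1)
  v <- numeric(400)
  v[c(101:160, 201:300)] <- 8
  v[161:200] <- 2
  tr <- coverage_track(list(chr1 = Rle(v)))
  tab <- gene_feature_table(tr, catal, m, pseudocount = 0)
  expect_equal(tab$mean_exon_cov, 8)
  expect_equal(tab$mean_intron_cov, 2)
  expect_equal(tab$log2_exon, 3)
  expect_equal(tab$log2_intron, 1)

  # zero coverage with pseudocount 1 -> log2 values 0
  tz <- coverage_track(list(chr1 = Rle(0, 400)))
  tabz <- gene_feature_table(tz, catal, m, pseudocount = 1)
  expect_equal(tabz$log2_exon, 0)
  expect_equal(tabz$log2_intron, 0)

  # single-exon gene has NA intron fields
  m1 <- toy_models(101, 200)
  t1 <- gene_feature_table(tr, derive_features(m1), m1)
  expect_true(is.na(t1$mean_intron_cov))
})

test_that("simulated per-gene means match the closed-form expectations", {
  sim <- shared_sim()
  tr <- simulate_rna_coverage(sim, "control", 1)
  catal <- derive_features(sim$models, min_length = 1)
  tab <- gene_feature_table(tr, catal, sim$models)
  truth <- sim$truth[match(tab$gene_id, sim$truth$gene_id), ]
  expressed <- truth$level_control > 0
  exp_exon <- sim$config$rna_depth * truth$level_control
  # relative error shrinks with feature length; compare in aggregate
  ratio <- tab$mean_exon_cov[expressed] / exp_exon[expressed]
  expect_lt(abs(median(ratio) - 1), 0.05)
  exp_int <- sim$config$rna_depth * sim$config$base_intron_fraction *
    truth$level_control
  ok <- expressed & !is.na(tab$mean_intron_cov)
  expect_lt(abs(median(tab$mean_intron_cov[ok] / exp_int[ok]) - 1), 0.15)
})

test_that("bedGraph output round-trips through the loader", {
  sim <- shared_sim()
  tr <- simulate_rna_coverage(sim, "control", 1)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.bedgraph")
  write_bedgraph(tr, p)
  tr2 <- load_track(p, format = "bedgraph",
                    chrom_lengths = sim$chrom_lengths, assay = "rna")
  for (cc in names(tr$cov))
    expect_equal(as.numeric(tr2$cov[[cc]]), as.numeric(tr$cov[[cc]]),
                 tolerance = 1e-8)
})
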