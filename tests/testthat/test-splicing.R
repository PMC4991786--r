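fake_record <- function(gene, exon, intron, outron = NA, condition = "x") {
  data.frame(gene_id = gene, condition = condition,
             mean_exon_cov = exon, mean_intron_cov = intron,
             mean_outron_cov = outron, stringsAsFactors = FALSE)
}

test_that("splicing ratio change captures pre-mRNA persistence", {
  ctrl <- fake_record("g1", exon = 8, intron = 2)
  trt <- fake_record("g1", exon = 4, intron = 2)
  r <- splicing_ratio(trt, ctrl)
  expect_equal(r$ratio_control, 0.25)
  expect_equal(r$ratio_treatment, 0.5)
  expect_equal(r$ratio_change, 2)

  # identical records: no change
  same <- splicing_ratio(ctrl, ctrl)
  expect_equal(same$ratio_change, 1)

  # outron numerator
  co <- fake_record("g1", exon = 8, intron = NA, outron = 2)
  to <- fake_record("g1", exon = 4, intron = NA, outron = 4)
  ro <- splicing_ratio(to, co, numerator = "outron")
  expect_equal(ro$ratio_change, 4)

  # control mRNA zero -> excluded, not infinite
  cz <- fake_record("g1", exon = 0, intron = 2)
  rz <- splicing_ratio(trt, cz)
  expect_true(rz$excluded)
  expect_true(is.na(rz$ratio_change))

  expect_error(splicing_ratio(fake_record("gX", 1, 1), ctrl), "mismatched")
})

test_that("ratio change is invariant to global track scaling", {
  ctrl <- fake_record(c("g1", "g2"), exon = c(8, 6), intron = c(2, 3))
  trt <- fake_record(c("g1", "g2"), exon = c(4, 6), intron = c(2, 6))
  r0 <- splicing_ratio(trt, ctrl)$ratio_change
  scale_tab <- function(tab, f) {
    tab$mean_exon_cov <- tab$mean_exon_cov * f
    tab$mean_intron_cov <- tab$mean_intron_cov * f
    tab
  }
  r1 <- splicing_ratio(scale_tab(trt, 7.3), scale_tab(ctrl, 0.2))$ratio_change
  expect_equal(r1, r0)
})

make_ct <- function(rows) {
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[[1]], condition = r[[2]], target = r[[3]],
               replicate = as.integer(r[[4]]), ct = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)))
  class(tab) <- c("CtTable", class(tab))
  tab
}

test_that("delta-delta-Ct recovers programmed shifts exactly", {
  base <- list(
    list("c1", "L4440", "18S", 1, 10), list("c1", "L4440", "geneA", 1, 20),
    list("t1", "rnai", "18S", 1, 10))
  # equal dCt -> level 1
  eq <- make_ct(c(base, list(list("t1", "rnai", "geneA", 1, 20))))
  r <- delta_delta_ct(eq, control_condition = "L4440")
  expect_equal(r$relative_level[r$condition == "rnai"], 1)
  expect_equal(r$relative_level[r$condition == "L4440"], 1)

  # target one cycle higher in treatment -> 0.5
  up1 <- make_ct(c(base, list(list("t1", "rnai", "geneA", 1, 21))))
  r <- delta_delta_ct(up1, control_condition = "L4440")
  expect_equal(r$relative_level[r$condition == "rnai"], 0.5)

  # reference one cycle higher in treatment, target unchanged -> 2
  refup <- make_ct(list(
    list("c1", "L4440", "18S", 1, 10), list("c1", "L4440", "geneA", 1, 20),
    list("t1", "rnai", "18S", 1, 11), list("t1", "rnai", "geneA", 1, 20)))
  r <- delta_delta_ct(refup, control_condition = "L4440")
  expect_equal(r$relative_level[r$condition == "rnai"], 2)
})

test_that("delta-delta-Ct is invariant to per-sample plate offsets", {
  tab <- make_ct(list(
    list("c1", "L4440", "18S", 1, 10.2), list("c1", "L4440", "gA", 1, 19.7),
    list("c2", "L4440", "18S", 1, 9.8), list("c2", "L4440", "gA", 1, 20.1),
    list("t1", "rnai", "18S", 1, 10.5), list("t1", "rnai", "gA", 1, 22.0),
    list("t2", "rnai", "18S", 1, 10.0), list("t2", "rnai", "gA", 1, 21.6)))
  r0 <- delta_delta_ct(tab, control_condition = "L4440")
  shifted <- tab
  offs <- c(c1 = 3.1, c2 = -0.7, t1 = 1.4, t2 = -2.2)
  shifted$ct <- shifted$ct + offs[shifted$sample]
  r1 <- delta_delta_ct(shifted, control_condition = "L4440")
  expect_equal(r1$relative_level, r0$relative_level)
  expect_equal(r1$sd_relative_level, r0$sd_relative_level)
})

test_that("technical replicates average on the Ct scale and errors name samples", {
  tab <- make_ct(list(
    list("c1", "L4440", "18S", 1, 10), list("c1", "L4440", "18S", 2, 12),
    list("c1", "L4440", "gA", 1, 20), list("c1", "L4440", "gA", 2, 22),
    list("t1", "rnai", "18S", 1, 11), list("t1", "rnai", "gA", 1, 21)))
  r <- delta_delta_ct(tab, control_condition = "L4440")
  # dCt: control (21 - 11) = 10, treatment (21 - 11) = 10 -> level 1
  expect_equal(r$relative_level[r$condition == "rnai"], 1)

  noref <- make_ct(list(
    list("c1", "L4440", "18S", 1, 10), list("c1", "L4440", "gA", 1, 20),
    list("t9", "rnai", "gA", 1, 21)))
  expect_error(delta_delta_ct(noref, control_condition = "L4440"), "t9")
})

test_that("qPCR pre-mRNA/mRNA ratios divide relative levels and flag undetected", {
  tab <- make_ct(list(
    list("c1", "L4440", "18S", 1, 10),
    list("c1", "L4440", "gA_pre", 1, 20), list("c1", "L4440", "gA_ex", 1, 18),
    list("t1", "rnai", "18S", 1, 10),
    # pre-mRNA up ~ log2(3) cycles, mRNA down 1 cycle
    list("t1", "rnai", "gA_pre", 1, 20 - log2(3)),
    list("t1", "rnai", "gA_ex", 1, 19)))
  r <- premrna_mrna_qpcr(tab, premrna_targets = list(gA = "gA_pre"),
                         mrna_targets = list(gA = "gA_ex"),
                         control_condition = "L4440")
  expect_equal(r$premrna_mrna_ratio[r$condition == "L4440"], 1)
  expect_equal(r$premrna_mrna_ratio[r$condition == "rnai"], 6)

  # maternal pattern: no pre-mRNA amplification anywhere -> ratio 0, flagged
  mat <- make_ct(list(
    list("c1", "L4440", "18S", 1, 10),
    list("c1", "L4440", "gM_pre", 1, NA), list("c1", "L4440", "gM_ex", 1, 18),
    list("t1", "rnai", "18S", 1, 10),
    list("t1", "rnai", "gM_pre", 1, NA), list("t1", "rnai", "gM_ex", 1, 18)))
  rm <- premrna_mrna_qpcr(mat, premrna_targets = list(gM = "gM_pre"),
                          mrna_targets = list(gM = "gM_ex"),
                          control_condition = "L4440")
  expect_true(all(rm$premrna_mrna_ratio == 0))
  expect_true(all(rm$undetected))

  expect_error(premrna_mrna_qpcr(tab, premrna_targets = list(gA = "gA_pre"),
                                 mrna_targets = list()),
               "absent from one target list")
})

test_that("simulated Ct tables recover the programmed relative levels", {
  sim <- shared_sim()
  q <- simulate_ct_table(sim)
  rel <- delta_delta_ct(q$table, control_condition = "L4440")
  trt_label <- sim$config$condition_labels[["treatment"]]
  for (i in seq_len(nrow(q$expected))) {
    ex <- q$expected[i, ]
    if (ex$condition != trt_label) next
    got <- rel$relative_level[rel$target == paste0(ex$gene_id, "_exon") &
                                rel$condition == ex$condition]
    expect_lt(abs(got / ex$true_relative_mrna - 1), 0.15)
  }
})
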