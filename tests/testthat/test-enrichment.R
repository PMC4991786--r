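# independent oracle: enumerate all C(N, n) draws via the hypergeometric pmf
# computed from raw binomial coefficients
enum_hyper <- function(N, K, n, k) {
  support <- max(0, n + K - N):min(n, K)
  pmf <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  list(p_enrich = sum(pmf[support >= k]), p_deplete = sum(pmf[support <= k]))
}

test_that("DE selection applies fold and q thresholds on both sides", {
  tab <- data.frame(
    gene_id = paste0("g", 1:6),
    log2fc = c(-1.5, 0.9, 2.0, -1.0, -3.0, 1.5),
    q = c(0.01, 0.001, 0.04, 0.2, 0.05, 0.06))
  sel <- suppressMessages(select_de_genes(tab))
  # hand enumeration: down needs log2fc <= -1 & q <= 0.05 -> g1, g5
  expect_setequal(sel$down, c("g1", "g5"))
  # up needs log2fc >= 1 & q <= 0.05 -> g3 only (g6 fails on q)
  expect_setequal(sel$up, "g3")
  expect_error(select_de_genes(tab, min_fold = 1), "min_fold")
})

test_that("DE tables parse in standard and Cuffdiff layouts", {
  dir <- withr::local_tempdir()
  std <- file.path(dir, "de.tsv")
  writeLines(c("gene_id\tlog2fc\tq", "g1\t-2\t0.001"), std)
  expect_equal(read_de_table(std)$log2fc, -2)

  cd <- file.path(dir, "gene_exp.diff")
  writeLines(c(paste("test_id", "gene_id", "gene", "locus", "sample_1",
                     "sample_2", "status", "value_1", "value_2",
                     "log2(fold_change)", "test_stat", "p_value", "q_value",
                     "significant", sep = "\t"),
               paste("x1", "g1", "g1", "chr1:1-2", "a", "b", "OK", "5", "1.2",
                     "-2.05", "-3", "0.0001", "0.002", "yes", sep = "\t")), cd)
  tab <- read_de_table(cd, layout = "cuffdiff")
  expect_equal(tab$gene_id, "g1")
  expect_equal(tab$q, 0.002)

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("gene\tfc", "g1\t2"), bad)
  expect_error(read_de_table(bad), "missing column")
})

test_that("catalog set algebra matches hand-worked examples", {
  lists <- list(germline = c("a", "b", "c"), neuronal = c("a", "b"),
                muscle = c("a", "b"), gut = "a",
                somatic_any = c("x", "y", "a"),
                germline_enriched_src = character(0),
                strict_maternal = c("b", "y"),
                strict_embryonic = c("e1", "e2"),
                chrX_all = "xg", silent_src = "s1",
                sperm_genes = character(0))
  cat <- build_catalog(lists)
  expect_equal(cat$ubiquitous, "a")
  expect_setequal(cat$soma_specific, c("x", "y"))
  # germline & maternal & not somatic -> b
  expect_equal(cat$germline_specific, "b")
  expect_equal(cat$embryo_expressed, c("e1", "e2"))

  # spermatogenesis genes subtracted from the enriched source
  lists$germline_enriched_src <- c("p", "q", "r")
  lists$sperm_genes <- "q"
  expect_setequal(build_catalog(lists)$germline_enriched, c("p", "r"))

  # empty strict-maternal empties the germline-specific class
  lists$strict_maternal <- character(0)
  expect_length(build_catalog(lists)$germline_specific, 0)

  expect_error(build_catalog(lists[-1]), "germline")
})

test_that("hypergeometric tails match exhaustive enumeration everywhere", {
  # exact fractions worked out by enumerating C(10,4) draws
  expect_equal(hypergeom_test(10, 5, 4, 4)$p_enrich, 5 / 210)
  expect_equal(hypergeom_test(10, 5, 4, 2)$p_enrich, 155 / 210)

  for (N in c(5, 9, 12)) for (K in 0:N) for (n in 0:N) {
    support <- max(0, n + K - N):min(n, K)
    for (k in support) {
      got <- hypergeom_test(N, K, n, k)
      want <- enum_hyper(N, K, n, k)
      expect_equal(got$p_enrich, want$p_enrich, tolerance = 1e-12)
      expect_equal(got$p_deplete, want$p_deplete, tolerance = 1e-12)
    }
  }
})

test_that("hypergeometric tails are monotone, cover the support, share the point mass", {
  N <- 40; K <- 12; n <- 15
  support <- max(0, n + K - N):min(n, K)
  pe <- vapply(support, function(k) hypergeom_test(N, K, n, k)$p_enrich,
               numeric(1))
  pd <- vapply(support, function(k) hypergeom_test(N, K, n, k)$p_deplete,
               numeric(1))
  expect_true(all(diff(pe) <= 1e-12))
  expect_true(all(diff(pd) >= -1e-12))
  expect_true(all(pe + pd >= 1 - 1e-12))  # both tails include P(X = k)
  expect_equal(sum(dhyper(support, K, N - K, n)), 1, tolerance = 1e-12)
  expect_equal(hypergeom_test(N, K, n, max(support))$p_deplete, 1)
  expect_error(hypergeom_test(10, 5, 4, 5), "support")
})

test_that("enrichment report computes expectation, ratio and tiers", {
  universe <- paste0("u", 1:1000)
  class_members <- universe[1:100]
  de <- c(universe[1:50], universe[101:250])  # n = 200, k = 50
  rep1 <- enrichment_report(de, universe, list(cls = class_members))
  expect_equal(rep1$expected, 20)
  expect_equal(rep1$obs_exp_ratio, 2.5)
  expect_equal(rep1$direction, "enriched")

  # observed equal to expected: ratio 1, no tier
  de2 <- c(universe[1:20], universe[101:280])
  rep2 <- enrichment_report(de2, universe, list(cls = class_members))
  expect_equal(rep2$obs_exp_ratio, 1)
  expect_equal(rep2$tier, "")

  # tier thresholds
  expect_equal(nascentr:::tier_for(1e-6), "**")
  expect_equal(nascentr:::tier_for(1e-11), "***")
  expect_equal(nascentr:::tier_for(0.009), "*")
  expect_equal(nascentr:::tier_for(0.02), "")

  expect_error(enrichment_report("zz", universe, list(cls = class_members)),
               "outside the universe")
  expect_error(enrichment_report(character(0), character(0), list()),
               "empty universe")
})

test_that("random DE draws trip the 0.01 tier at the nominal rate", {
  set.seed(101)
  universe <- paste0("u", 1:800)
  classes <- list(cls = universe[1:120])
  hits <- 0L
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    de <- sample(universe, 150)
    r <- enrichment_report(de, universe, classes)
    if (r$tier != "") hits <- hits + 1L
  }
  # both tails tested at 0.01 -> overall rate ~ 0.02; allow binomial 99% slack
  rate <- hits / n_sim
  expect_lt(rate, 0.02 + 2.58 * sqrt(0.02 * 0.98 / n_sim))
})

test_that("programmed class depletion of transcripts is flagged on simulated data", {
  sim <- memo("enrich_sim", function() simulate_genome(sim_config(seed = 2024)))
  de <- simulate_de_table(sim)
  sel <- suppressMessages(select_de_genes(de))
  cat <- build_catalog(truth_class_roles(sim))
  rep_down <- enrichment_report(sel$down, de$gene_id, cat)
  emb <- rep_down[rep_down$class == "embryo_expressed", ]
  expect_equal(emb$direction, "enriched")
  expect_gt(emb$obs_exp_ratio, 1.5)
  expect_true(emb$tier != "")
})
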