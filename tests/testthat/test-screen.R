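mk_table <- function(values, varieties, stages) {
  samples <- data.frame(sample = colnames(values), variety = varieties,
                        stage = stages, stringsAsFactors = FALSE)
  wrkykit:::expression_table(values, samples)
}

test_that("log2 fold change uses pseudocounted replicate means", {
  vals <- matrix(c(1, 1, 7, 7,
                   4, 4, 4, 4,
                   0, 0, 0, 0), nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("wf1", "wf2", "rf1", "rf2")))
  tab <- mk_table(vals, c("WF", "WF", "RF", "RF"), rep("bud", 4))
  ct <- contrast("WFvsRF", c("wf1", "wf2"), c("rf1", "rf2"), "bud")
  fc <- log2_fold_change(tab, ct)
  expect_equal(unname(fc), c(2, 0, 0))  # log2(8/2), identity, all-zero gene

  # swapping baseline and treatment negates every fold change
  rev_ct <- contrast("RFvsWF", c("rf1", "rf2"), c("wf1", "wf2"), "bud")
  expect_equal(log2_fold_change(tab, rev_ct), -fc, ignore_attr = TRUE)

  bad <- contrast("x", "wf1", "nope", "bud")
  expect_error(log2_fold_change(tab, bad), "nope")
  expect_error(contrast("x", "s1", "s1", "bud"), "overlap")
})

test_that("DEG calling is boundary-inclusive and threshold-monotone", {
  fc <- c(a = 1.0, b = -0.99, c = 2.5, d = -1.0, e = 0.2)
  degs <- call_degs(fc, 1.0)
  expect_setequal(degs$up, c("a", "c"))
  expect_setequal(degs$down, "d")
  expect_false("b" %in% c(degs$up, degs$down))
  stricter <- call_degs(fc, 1.5)
  expect_true(all(stricter$up %in% degs$up))
  expect_true(all(stricter$down %in% degs$down))
  expect_length(intersect(degs$up, degs$down), 0)
})

test_that("candidate screen intersects the two contrasts per stage", {
  d1 <- deg_set_from_lists(c("a", "b", "c"), "x", "WFvsRF", "bud")
  d2 <- deg_set_from_lists(c("b", "c", "d"), c("x", "y"), "WFvsPF", "bud")
  res <- screen_candidates(d1, d2)
  expect_equal(res$positive, c("b", "c"))
  expect_equal(res$negative, "x")

  d3 <- deg_set_from_lists("b", "x", "WFvsPF", "full_bloom")
  expect_error(screen_candidates(d1, d3), "stage mismatch")
})

test_that("published candidate lists give 17 bud and 9 bloom candidates", {
  sc <- fixture_candidate_screen()
  expect_equal(length(sc$bud$positive) + length(sc$bud$negative), 17)
  expect_equal(length(sc$bud$positive), 4)
  expect_equal(length(sc$full_bloom$positive) + length(sc$full_bloom$negative), 9)
  expect_equal(length(sc$full_bloom$negative), 5)
  expect_equal(sc$both_stages, "RsWRKY26")
})

test_that("planted candidates are recovered from noisy FPKM tables", {
  hits <- sapply(1:20, function(seed) {
    sim <- gen_fpkm_table(100, 10, 10, fold = 8, noise_sigma = 0.25,
                          replicates = 3, seed = seed)
    meta <- sim$table$samples
    pick <- function(v) meta$sample[meta$variety == v & meta$stage == "bud"]
    res <- screen_candidates(
      degs_for_contrast(sim$table, contrast("WFvsRF", pick("WF"), pick("RF"), "bud")),
      degs_for_contrast(sim$table, contrast("WFvsPF", pick("WF"), pick("PF"), "bud")))
    found <- c(res$positive, res$negative)
    truth <- c(sim$truth$positive, sim$truth$negative)
    c(precision = mean(found %in% truth), recall = mean(truth %in% found))
  })
  expect_gte(mean(hits["precision", ]), 0.95)
  expect_gte(mean(hits["recall", ]), 0.95)
})

test_that("ddCt arithmetic follows the closed form", {
  ct <- data.frame(sample = c("w1", "w2", "r1", "r2"),
                   group = c("WF", "WF", "RF", "RF"),
                   target = c(25, 25, 24, 24),
                   ref1 = c(20, 20, 20, 20),
                   ref2 = c(22, 22, 22, 22))
  fold <- ddct_fold_change(ct, c("ref1", "ref2"), calibrator = "WF")
  # dCt uses the mean reference Ct of 21; ddCt(RF) = -1 so fold = 2
  expect_equal(fold[["WF"]], 1)
  expect_equal(fold[["RF"]], 2)

  ct$target[1] <- NA
  expect_error(ddct_fold_change(ct, c("ref1", "ref2"), "WF"), "missing Ct.*w1")
  expect_error(ddct_fold_change(ct, c("ref1", "ref2"), "XX"), "calibrator")
})

test_that("enrichment p-values match the hypergeometric enumeration oracle", {
  set.seed(47)
  population <- sprintf("g%04d", 1:1000)
  term_map <- data.frame(
    term = rep(sprintf("T%02d", 1:20), each = 10),
    gene = sample(population, 200, replace = FALSE),
    stringsAsFactors = FALSE)
  study <- unique(c(sample(term_map$gene[term_map$term == "T01"], 3),
                    sample(population, 47)))
  res <- fisher_enrichment(study, population, term_map)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 oracle_hyper_upper(res$k[i], res$K[i], res$N[i], res$n[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(res$padj >= res$p - 1e-15))
  expect_true(all(res$padj <= 1))

  # k = 0 has upper-tail probability 1
  lonely <- fisher_enrichment("g0001", population,
                              data.frame(term = "T", gene = c("g0999", "g0998")))
  expect_equal(lonely$p, 1)
  expect_equal(lonely$padj, lonely$p)  # single tested term: no correction

  expect_error(fisher_enrichment("zz", population, term_map), "outside")
})
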