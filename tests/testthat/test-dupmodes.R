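mk_loci <- function(n_per_chrom, chroms = c("chrA", "chrB")) {
  df <- do.call(rbind, lapply(chroms, function(ch) {
    data.frame(gene_id = paste0(ch, "_", sprintf("%03d", seq_len(n_per_chrom))),
               chrom = ch, start = seq_len(n_per_chrom) * 100,
               end = seq_len(n_per_chrom) * 100 + 50, strand = "+",
               stringsAsFactors = FALSE)
  }))
  wrkykit:::compute_ranks(df)
}

chain_pairs <- function(loci, ranks_a, ranks_b) {
  data.frame(
    gene_a = loci$gene_id[loci$chrom == "chrA"][ranks_a + 1],
    gene_b = loci$gene_id[loci$chrom == "chrB"][ranks_b + 1],
    stringsAsFactors = FALSE)
}

test_that("greedy chaining finds planted chains and honors thresholds", {
  loci <- mk_loci(80)
  blocks <- detect_collinear_blocks(chain_pairs(loci, 0:5, 10:15), loci)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$n_anchors, 6)

  expect_length(detect_collinear_blocks(chain_pairs(loci, 0:3, 10:13), loci), 0)

  # one rank gap of 30 splits the chain; both halves fall below min_anchors
  split_chain <- chain_pairs(loci, c(0:3, 34:37), c(10:13, 44:47))
  expect_length(detect_collinear_blocks(split_chain, loci), 0)

  # descending side-B progression is a valid direction
  blocks <- detect_collinear_blocks(chain_pairs(loci, 0:5, 15:10), loci)
  expect_length(blocks, 1)

  bad <- data.frame(gene_a = "nope", gene_b = loci$gene_id[1])
  expect_error(detect_collinear_blocks(bad, loci), "nope")
})

test_that("pair rules fire in priority order", {
  loci <- mk_loci(80)
  anchors <- chain_pairs(loci, 0:5, 10:15)
  tandem <- data.frame(gene_a = "chrA_050", gene_b = "chrA_051")
  prox <- data.frame(gene_a = "chrA_060", gene_b = "chrA_065")
  pairs <- rbind(anchors, tandem, prox)
  blocks <- detect_collinear_blocks(pairs, loci)
  called <- classify_pairs(pairs, blocks, loci)
  expect_equal(called$mode[1:6], rep("WGD", 6))
  expect_equal(called$mode[7], "TANDEM")
  expect_equal(called$mode[8], "PROXIMAL")
})

test_that("pair classification agrees with the independent rule oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    loci <- mk_loci(100)
    n <- 40
    pairs <- data.frame(gene_a = sample(loci$gene_id, n),
                        gene_b = sample(loci$gene_id, n),
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$gene_a != pairs$gene_b, ]
    pairs <- wrkykit:::canonicalize_pairs(cbind(pairs, score = NA_real_))
    blocks <- detect_collinear_blocks(pairs, loci)
    called <- classify_pairs(pairs, blocks, loci)
    oracle <- mapply(oracle_pair_mode, called$gene_a, called$gene_b,
                     MoreArgs = list(blocks = blocks, loci = loci))
    expect_equal(called$mode, unname(oracle))
    # partition: every pair receives exactly one of the five modes
    expect_true(all(called$mode %in% c("WGD", "TANDEM", "PROXIMAL",
                                       "TRANSPOSED", "DISPERSED")))
  }
})

test_that("gene modes take the highest-priority mode among a gene's pairs", {
  calls <- data.frame(gene_a = c("g1", "g1", "g2"),
                      gene_b = c("g2", "g3", "g4"),
                      mode = c("DISPERSED", "WGD", "TANDEM"),
                      stringsAsFactors = FALSE)
  gm <- assign_gene_modes(calls)
  expect_equal(gm$mode[gm$gene_id == "g1"], "WGD")
  expect_equal(gm$mode[gm$gene_id == "g2"], "TANDEM")
  expect_equal(gm$mode[gm$gene_id == "g4"], "TANDEM")
  expect_false("g5" %in% gm$gene_id)

  # adding a WGD pair never demotes a gene's mode
  more <- rbind(calls, data.frame(gene_a = "g2", gene_b = "g9", mode = "WGD"))
  gm2 <- assign_gene_modes(more)
  prio <- function(m) match(m, c("WGD", "TANDEM", "PROXIMAL", "TRANSPOSED",
                                 "DISPERSED"))
  shared <- intersect(gm$gene_id, gm2$gene_id)
  expect_true(all(prio(gm2$mode[match(shared, gm2$gene_id)]) <=
                    prio(gm$mode[match(shared, gm$gene_id)])))
})

test_that("planted duplication modes are recovered on synthetic genomes", {
  for (seed in 1:3) {
    sim <- gen_duplicated_genome(c(WGD = 10, TANDEM = 10, PROXIMAL = 10,
                                   TRANSPOSED = 10, DISPERSED = 10),
                                 seed = seed)
    ana <- dup_mode_analysis(sim$pairs, sim$loci)
    expect_gte(mean(ana$pair_modes$mode == sim$truth$mode), 0.95)
    gm <- ana$gene_modes
    expect_true(all(table(gm$gene_id) == 1))
  }
})

test_that("published family-table duplication types tally as printed", {
  tal <- fixture_dup_tally()
  expect_equal(unclass(tal)[c("WGD", "Tandem", "Proximal", "Transposed",
                              "Dispersed")],
               c(WGD = 27, Tandem = 5, Proximal = 1, Transposed = 12,
                 Dispersed = 12), ignore_attr = TRUE)
  expect_equal(attr(tal, "wgd_pct"), 100 * 27 / 57, tolerance = 1e-12)
  expect_equal(sum(tal), 57)
})
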