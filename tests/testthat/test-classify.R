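mk_ann <- function(id, n_domains, zf_types, cc_spacers = NA, windows = NA,
                   partial = FALSE) {
  dom <- data.frame(
    hepta_start = seq_len(n_domains) * 100,
    motif7 = "WRKYGQK", mismatches = 0L,
    partial = rep_len(partial, n_domains),
    zf_type = rep_len(zf_types, n_domains),
    c1 = NA_integer_, c2 = NA_integer_, h1 = NA_integer_, last = NA_integer_,
    cc_spacer = rep_len(cc_spacers, n_domains),
    post_c2_window = rep_len(windows, n_domains),
    stringsAsFactors = FALSE)
  dom$complete <- !is.na(dom$zf_type) & !dom$partial
  structure(list(protein_id = id, domains = dom,
                 n_complete = sum(dom$complete),
                 zf_lost = any(is.na(dom$zf_type))),
            class = "wrky_annotation")
}

test_that("structural ladder assigns groups in rule order", {
  expect_equal(classify_structural(mk_ann("a", 2, "C2H2", 4, "AAAAAAAAAAAA"))$label, "I")
  expect_equal(classify_structural(mk_ann("b", 1, "C2HC", 7, "AAAAAAAAAAAA"))$label, "III")
  expect_equal(classify_structural(mk_ann("c", 1, "C2H2", 4, "AAAAAAAAAAAA"))$label, "IIc")
  expect_equal(classify_structural(mk_ann("d", 1, NA_character_))$label, "UC")
  # C2HC outranks domain count 1; two domains with C2HC and no C2H2 is III
  expect_equal(classify_structural(mk_ann("e", 2, "C2HC", 7, "AAAAAAAAAAAA"))$label, "III")
  expect_error(classify_structural(
    structure(list(protein_id = "z",
                   domains = mk_ann("z", 1, "C2H2", 5, "PVKKKLQAAAAA")$domains[0, ],
                   n_complete = 0, zf_lost = FALSE),
              class = "wrky_annotation")), "no WRKY domain")
})

test_that("subgroup signatures decide IIa/IIb/IId/IIe with Hamming fallback", {
  expect_equal(classify_structural(mk_ann("a", 1, "C2H2", 5, "PVKKKLQAAAAA"))$label, "IIa")
  expect_equal(classify_structural(mk_ann("a2", 1, "C2H2", 5, "PVKKKVQAAAAA"))$label, "IIa")
  expect_equal(classify_structural(mk_ann("b", 1, "C2H2", 5, "PVRKQVQAAAAA"))$label, "IIb")
  expect_equal(classify_structural(mk_ann("d", 1, "C2H2", 5, "PARKHVEAAAAA"))$label, "IId")
  expect_equal(classify_structural(mk_ann("e", 1, "C2H2", 5, "PARKMVDAAAAA"))$label, "IIe")
  # two mismatches from the IId signature still map to IId
  expect_equal(classify_structural(mk_ann("f", 1, "C2H2", 5, "PARKHAAAAAAA"))$label, "IId")
  # beyond the tolerance: UC
  res <- classify_structural(mk_ann("g", 1, "C2H2", 5, "AAAAAAAAAAAA"))
  expect_equal(res$label, "UC")
  # with the tolerance lifted the nearest signatures are PARKHVE/PARKQVE
  # (Hamming 6, sharing the A); the IId < IIe lexical tie-break applies
  expect_equal(classify_structural(mk_ann("g", 1, "C2H2", 5, "AAAAAAAAAAAA"),
                                   max_mismatch = 7)$label, "IId")
})

test_that("every annotated protein gets exactly one label from the vocabulary", {
  sim <- gen_wrky_proteome(4, seed = 8, degrade_frac = 0.5)
  res <- classify_proteins(annotate_wrky_proteome(sim$seqs))
  expect_equal(nrow(res), nrow(sim$truth))
  expect_true(all(res$label %in% c("I", "IIa", "IIb", "IIc", "IId", "IIe",
                                   "III", "UC")))
  s <- summarize_groups(res)
  expect_equal(sum(s$subgroups), s$total)
  expect_equal(s$main[["II"]], sum(s$subgroups[c("IIa", "IIb", "IIc", "IId", "IIe")]))
})

test_that("tree transfer relabels UC by nearest labeled leaf with tie-breaks", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  lf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("((u:1,a:1):1,b:5);", tf)
  writeLines(c("leaf\tgroup", "a\tIId", "b\tIII"), lf)
  lt <- read_newick(tf, lf)
  res <- data.frame(
    protein_id = "u", label = "UC", basis = "structural", evidence = "",
    stringsAsFactors = FALSE)
  out <- transfer_labels(lt, res)
  expect_equal(out$label, "IId")
  expect_equal(out$basis, "tree")

  # equidistant IIc and IIa neighbors: lexically smaller label wins
  writeLines("(a:1,u:1,c:1);", tf)
  writeLines(c("leaf\tgroup", "a\tIIc", "c\tIIa"), lf)
  out <- transfer_labels(read_newick(tf, lf), res)
  expect_equal(out$label, "IIa")

  # structurally classified labels are never changed
  res2 <- data.frame(protein_id = c("u", "a"), label = c("UC", "I"),
                     basis = "structural", evidence = "",
                     stringsAsFactors = FALSE)
  writeLines(c("leaf\tgroup", "c\tIIe"), lf)
  out2 <- transfer_labels(read_newick(tf, lf), res2)
  expect_equal(out2$label[out2$protein_id == "a"], "I")
  expect_equal(out2$label[out2$protein_id == "u"], "I")  # nearest is leaf a

  res3 <- data.frame(protein_id = "ghost", label = "UC", basis = "structural",
                     evidence = "", stringsAsFactors = FALSE)
  expect_error(transfer_labels(read_newick(tf, lf), res3), "ghost")
})

test_that("group summary reproduces the published azalea family tallies", {
  cs <- fixture_classification_summary()
  expect_equal(cs$summary$main[c("I", "II", "III")], c(I = 12, II = 35, III = 10))
  expect_equal(cs$summary$subgroups[c("IIa", "IIb", "IIc", "IId", "IIe")],
               c(IIa = 5, IIb = 7, IIc = 12, IId = 5, IIe = 6))
  expect_equal(cs$summary$total, 57)
  expect_equal(cs$n_lost, 4)
  s0 <- summarize_groups(character(0))
  expect_equal(sum(s0$subgroups), 0)
  expect_equal(s0$total, 0)
})
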