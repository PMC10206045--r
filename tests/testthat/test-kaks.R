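test_that("backtranslate maps residues to codons and gaps to ---", {
  aln <- c(p1 = "M-A", p2 = "MKA")
  cds <- c(p1 = "ATGGCT", p2 = "ATGAAAGCC")
  ca <- backtranslate(aln, cds)
  expect_equal(paste(ca$codons1, collapse = ""), "ATG---GCT")
  expect_equal(paste(ca$codons2, collapse = ""), "ATGAAAGCC")

  expect_error(backtranslate(c(p1 = "M-A", p2 = "MKA"),
                             c(p1 = "ATGTAAGCT", p2 = "ATGAAAGCC")),
               "stop codon.*index 2")
  expect_error(backtranslate(aln, c(p1 = "ATGGCTGCT", p2 = "ATGAAAGCC")),
               "does not match")
  expect_error(backtranslate(aln, c(p1 = "ATGTGT", p2 = "ATGAAAGCC")),
               "mismatch.*residue 2")
  # terminal stop codons are stripped silently
  ca2 <- backtranslate(aln, c(p1 = "ATGGCTTAA", p2 = "ATGAAAGCCTGA"))
  expect_equal(ca2$codons1, ca$codons1)
})

test_that("back-translation round-trips through translation", {
  set.seed(31)
  gc <- Biostrings::GENETIC_CODE
  for (rep in 1:10) {
    codons <- random_codons(sample(5:30, 1))
    prot <- paste(gc[codons], collapse = "")
    gapped <- strsplit(prot, "")[[1]]
    ins <- sort(sample(seq_along(gapped), 3))
    gapped_a <- paste(append(gapped, rep("-", 3), after = ins[1]), collapse = "")
    aln <- setNames(c(gapped_a, paste0(prot, "---")), c("x", "y"))
    ca <- backtranslate(aln, setNames(rep(paste(codons, collapse = ""), 2),
                                      c("x", "y")))
    back <- ca$codons1[ca$codons1 != "---"]
    expect_equal(paste(gc[back], collapse = ""), prot)
  }
})

test_that("identical sequences give zero distances and an undefined ratio", {
  seqs <- paste(random_codons(20), collapse = "")
  r <- ng86_pair(codon_alignment(seqs, seqs))
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))
  expect_equal(r$category, "undefined")
})

test_that("a single synonymous third-position change gives Sd=1, Ka=0", {
  set.seed(7)
  codons <- rep("GGA", 20)  # glycine: all third-position changes synonymous
  mut <- codons
  mut[5] <- "GGG"
  r <- ng86_pair(codon_alignment(paste(codons, collapse = ""),
                                 paste(mut, collapse = "")))
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_lt(r$Ka, r$Ks)
})

test_that("NG86 is symmetric and conserves sites", {
  set.seed(13)
  for (rep in 1:10) {
    a <- paste(random_codons(15), collapse = "")
    b <- paste(random_codons(15), collapse = "")
    r1 <- ng86_pair(codon_alignment(a, b))
    r2 <- ng86_pair(codon_alignment(b, a))
    expect_equal(r1[c("S", "N", "Sd", "Nd", "Ka", "Ks")],
                 r2[c("S", "N", "Sd", "Nd", "Ka", "Ks")])
    expect_equal(r1$S + r1$N, 3 * r1$n_codons, tolerance = 1e-9)
  }
})

test_that("counts equal the brute-force pathway-enumeration oracle", {
  set.seed(19)
  for (rep in 1:200) {
    n <- sample(1:5, 1)
    a <- random_codons(n)
    b <- random_codons(n)
    r <- ng86_pair(codon_alignment(paste(a, collapse = ""),
                                   paste(b, collapse = "")))
    o <- oracle_ng86(a, b)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
    expect_equal(r$S, o$S, tolerance = 1e-12)
    expect_equal(r$N, o$N, tolerance = 1e-12)
    expect_equal(r$n_codons, o$n_codons)
  }
})

test_that("selection categories follow the neutral band", {
  expect_equal(selection_category(0.3), "purifying")
  expect_equal(selection_category(1.0), "neutral")
  expect_equal(selection_category(1.04), "neutral")
  expect_equal(selection_category(1.2), "positive")
  expect_equal(selection_category(NA_real_), "undefined")
  expect_error(selection_category(-0.1), "negative")
})

test_that("families evolved under purifying selection all show Ka/Ks < 1", {
  sim <- gen_codon_pairs(15, 300, omega = 0.2, branch_length = 0.3, seed = 23)
  ratios <- vapply(sim$alignments, function(a) ng86_pair(a)$ratio, numeric(1))
  defined <- ratios[!is.na(ratios)]
  expect_gt(length(defined), 0)
  expect_true(all(defined < 1))
})
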