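# Seeded generators for every input class the pipeline consumes. Each
# generator is a pure function of its parameters and seed (the caller's RNG
# state is restored on exit) and returns planted truth sufficient to score
# the downstream stage.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# flank/spacer alphabet excludes C, H and W so that planted motifs are the
# only zinc-finger and heptapeptide matches (no rejection sampling needed)
SAFE_AA <- setdiff(AA20, c("C", "H", "W"))

rand_aa <- function(n) paste(sample(SAFE_AA, n, replace = TRUE), collapse = "")

build_zinc_finger <- function(subgroup) {
  post23 <- function(sig = "") paste0(sig, rand_aa(23L - nchar(sig)))
  switch(subgroup,
    I   = paste0("C", rand_aa(4), "C", post23(), "H", rand_aa(1), "H"),
    IIc = paste0("C", rand_aa(4), "C", post23(), "H", rand_aa(1), "H"),
    IIa = paste0("C", rand_aa(5), "C",
                 post23(sample(SUBGROUP_SIGNATURES$IIa, 1)), "H", rand_aa(1), "H"),
    IIb = paste0("C", rand_aa(5), "C",
                 post23(SUBGROUP_SIGNATURES$IIb), "H", rand_aa(1), "H"),
    IId = paste0("C", rand_aa(5), "C",
                 post23(SUBGROUP_SIGNATURES$IId), "H", rand_aa(1), "H"),
    IIe = paste0("C", rand_aa(5), "C",
                 post23(sample(SUBGROUP_SIGNATURES$IIe, 1)), "H", rand_aa(1), "H"),
    III = paste0("C", rand_aa(7), "C", post23(), "H", rand_aa(1), "C"),
    stopf("no zinc-finger grammar for %s", subgroup))
}

build_domain_unit <- function(subgroup, hepta = CANONICAL_HEPTA,
                              with_zf = TRUE) {
  linker <- rand_aa(sample(8:15, 1))
  if (with_zf) paste0(hepta, linker, build_zinc_finger(subgroup))
  else paste0(hepta, linker)
}

#' Generate a synthetic WRKY proteome with planted subgroup signatures
#'
#' For each class (I, IIa-IIe, III and a zinc-finger-lost class) proteins
#' carry the canonical heptapeptide and the class's zinc-finger grammar
#' embedded in random flanks. Flank and spacer residues are drawn from an
#' alphabet without C, H or W, so the planted motifs are provably the only
#' matches. Group I proteins carry two domain units. A fraction of
#' proteins can be degraded: either a variant heptapeptide (one mismatch;
#' still classifiable) or a lost zinc finger (expected label UC).
#'
#' @param n_per_subgroup proteins per class.
#' @param flank_len flank length in residues.
#' @param seed RNG seed.
#' @param degrade_frac fraction of proteins (per class, rounded down) that
#'   receive a degradation.
#' @return list with `seqs` (named protein vector) and `truth`
#'   (data.frame: id, subgroup, degradation, expected_label).
#' @export
gen_wrky_proteome <- function(n_per_subgroup = 2L, flank_len = 40L, seed = 1L,
                              degrade_frac = 0) {
  stopifnot(n_per_subgroup >= 1)
  classes <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III", "lost")
  with_seed(seed, {
    seqs <- character(); truth <- list()
    for (cl in classes) {
      n_deg <- floor(n_per_subgroup * degrade_frac)
      for (k in seq_len(n_per_subgroup)) {
        id <- sprintf("syn_%s_%02d", cl, k)
        degradation <- "none"
        hepta <- CANONICAL_HEPTA
        lose_zf <- cl == "lost"
        if (cl != "lost" && k <= n_deg) {
          degradation <- sample(c("variant_hepta", "lost_zf"), 1)
          if (degradation == "variant_hepta") hepta <- "WRKYGEK"
          else lose_zf <- TRUE
        }
        base_sub <- if (cl == "lost") "IIc" else cl
        if (cl == "I" && !lose_zf) {
          body <- paste0(build_domain_unit("I", hepta), rand_aa(flank_len),
                         build_domain_unit("I"))
        } else {
          body <- build_domain_unit(base_sub, hepta, with_zf = !lose_zf)
        }
        seqs[id] <- paste0(rand_aa(flank_len), body, rand_aa(flank_len))
        expected <- if (lose_zf) "UC" else if (cl == "lost") "UC" else cl
        truth[[length(truth) + 1L]] <- data.frame(
          id = id, subgroup = cl, degradation = degradation,
          expected_label = expected, stringsAsFactors = FALSE)
      }
    }
    list(seqs = seqs, truth = do.call(rbind, truth))
  })
}

NONSTOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

evolve_codons <- function(codons, omega, branch_length) {
  n_prop <- rpois(1, branch_length * 3 * length(codons))
  realized_syn <- 0L; realized_nonsyn <- 0L
  for (i in seq_len(n_prop)) {
    ci <- sample.int(length(codons), 1)
    pos <- sample.int(3L, 1)
    cur <- codons[ci]
    nt <- sample(setdiff(NUCS, substr(cur, pos, pos)), 1)
    cand <- cur
    substr(cand, pos, pos) <- nt
    if (is_stop(cand)) next
    syn <- codon_aa(cand) == codon_aa(cur)
    if (syn || runif(1) < omega) {
      codons[ci] <- cand
      if (syn) realized_syn <- realized_syn + 1L
      else realized_nonsyn <- realized_nonsyn + 1L
    }
  }
  list(codons = codons, syn = realized_syn, nonsyn = realized_nonsyn)
}

#' Generate codon-sequence pairs evolved under a planted dN/dS
#'
#' An ancestral codon sequence is mutated independently along two branches;
#' proposed single-nucleotide changes are accepted with probability 1 when
#' synonymous and `omega` when nonsynonymous, and changes creating stop
#' codons are rejected. `branch_length` is the expected number of proposed
#' changes per nucleotide site per branch, so realized divergence is lower
#' than the proposal intensity whenever `omega < 1`.
#'
#' @param n_pairs number of pairs.
#' @param n_codons codons per sequence.
#' @param omega planted dN/dS.
#' @param branch_length proposal intensity per site per branch.
#' @param seed RNG seed.
#' @return list with `alignments` (list of `codon_alignment`) and `truth`
#'   (data.frame: pair, realized synonymous/nonsynonymous counts per
#'   branch summed).
#' @export
gen_codon_pairs <- function(n_pairs = 10L, n_codons = 300L, omega = 0.2,
                            branch_length = 0.2, seed = 1L) {
  stopifnot(omega > 0, branch_length >= 0)
  with_seed(seed, {
    alns <- list(); truth <- list()
    for (p in seq_len(n_pairs)) {
      anc <- sample(NONSTOP_CODONS, n_codons, replace = TRUE)
      b1 <- evolve_codons(anc, omega, branch_length)
      b2 <- evolve_codons(anc, omega, branch_length)
      id <- sprintf("pair%03d", p)
      alns[[id]] <- codon_alignment(paste(b1$codons, collapse = ""),
                                    paste(b2$codons, collapse = ""), id = id)
      truth[[p]] <- data.frame(pair = id, syn = b1$syn + b2$syn,
                               nonsyn = b1$nonsyn + b2$nonsyn)
    }
    list(alignments = alns, truth = do.call(rbind, truth))
  })
}

#' Generate a gene order with planted duplication modes
#'
#' Background genes are laid out on six chromosomes. WGD pairs are planted
#' as collinear chains of at least five anchors between chr1 and chr2;
#' tandem pairs are rank-adjacent and proximal pairs sit at rank gaps of
#' 2-10 on their own chromosomes; transposed pairs link one WGD-chain
#' anchor to a distant locus; dispersed pairs link loci on two otherwise
#' unused chromosomes. Planted features are spaced further apart than the
#' default chaining gap so they cannot merge.
#'
#' @param n_per_mode named integer vector over WGD/TANDEM/PROXIMAL/
#'   TRANSPOSED/DISPERSED (a single number recycles to all five).
#' @param n_background total background genes (at least 900).
#' @param seed RNG seed.
#' @return list with `loci` (ranked gene table), `pairs` and `truth`
#'   (pairs plus planted `mode`).
#' @export
gen_duplicated_genome <- function(n_per_mode = 5L, n_background = 1500L,
                                  seed = 1L) {
  if (length(n_per_mode) == 1L) {
    n_per_mode <- setNames(rep(as.integer(n_per_mode), 5), DUP_MODES)
  }
  stopifnot(all(DUP_MODES %in% names(n_per_mode)),
            n_per_mode[["WGD"]] == 0 || n_per_mode[["WGD"]] >= 5,
            n_per_mode[["TRANSPOSED"]] <= 2 * n_per_mode[["WGD"]],
            n_background >= 900)
  with_seed(seed, {
    n_chrom <- 6L
    # every chromosome must fit its planted layout (features are spaced
    # wider than the default chaining gap, so room grows with the counts)
    need <- max(
      n_per_mode[["WGD"]] + 40L * max(1L, ceiling(n_per_mode[["WGD"]] / 5)),
      40L * n_per_mode[["TANDEM"]] + 15L,
      40L * n_per_mode[["PROXIMAL"]] + 25L,
      30L * (n_per_mode[["TRANSPOSED"]] + n_per_mode[["DISPERSED"]]) + 65L)
    per_chrom <- max(need, n_background %/% n_chrom)
    loci <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
      data.frame(gene_id = sprintf("g%d_%04d", ch, seq_len(per_chrom)),
                 chrom = sprintf("chr%d", ch),
                 start = seq_len(per_chrom) * 1000L + 1L,
                 end = seq_len(per_chrom) * 1000L + 500L,
                 strand = "+", stringsAsFactors = FALSE)
    }))
    loci <- compute_ranks(loci)
    gene_at <- function(ch, rank) sprintf("g%d_%04d", ch, rank + 1L)
    pairs <- list()
    add_pair <- function(a, b, mode) {
      pairs[[length(pairs) + 1L]] <<- data.frame(
        gene_a = min(a, b), gene_b = max(a, b), mode = mode,
        stringsAsFactors = FALSE)
    }
    # WGD: chains of >=5 consecutive anchors between chr1 and chr2,
    # chains spaced 40 ranks apart (> default max_rank_gap of 25)
    n_wgd <- n_per_mode[["WGD"]]
    wgd_anchor_a <- character()
    if (n_wgd > 0) {
      sizes <- rep(5L, n_wgd %/% 5L)
      rem <- n_wgd %% 5L
      if (rem > 0) sizes[length(sizes)] <- sizes[length(sizes)] + rem
      off <- 0L
      for (s in sizes) {
        for (j in seq_len(s) - 1L) {
          a <- gene_at(1L, off + j); b <- gene_at(2L, off + j)
          add_pair(a, b, "WGD")
          wgd_anchor_a <- c(wgd_anchor_a, a)
        }
        off <- off + s + 40L
      }
    }
    # tandem on chr3, adjacent ranks, spaced beyond the chaining gap so
    # consecutive tandem pairs can never chain into a block
    for (k in seq_len(n_per_mode[["TANDEM"]])) {
      r <- 10L + (k - 1L) * 40L
      add_pair(gene_at(3L, r), gene_at(3L, r + 1L), "TANDEM")
    }
    # proximal on chr4 at rank gaps 2-10
    for (k in seq_len(n_per_mode[["PROXIMAL"]])) {
      r <- 10L + (k - 1L) * 40L
      add_pair(gene_at(4L, r), gene_at(4L, r + sample(2:10, 1)), "PROXIMAL")
    }
    # transposed: one WGD anchor, one distant chr5 locus (spaced 30 ranks
    # so transposed pairs never chain among themselves)
    for (k in seq_len(n_per_mode[["TRANSPOSED"]])) {
      add_pair(wgd_anchor_a[k], gene_at(5L, (k - 1L) * 30L), "TRANSPOSED")
    }
    # dispersed: chr5 x chr6 loci far from everything
    disp_base <- n_per_mode[["TRANSPOSED"]] * 30L + 50L
    for (k in seq_len(n_per_mode[["DISPERSED"]])) {
      add_pair(gene_at(5L, disp_base + (k - 1L) * 30L),
               gene_at(6L, (k - 1L) * 30L + sample(0:10, 1)), "DISPERSED")
    }
    truth <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(gene_a = character(), gene_b = character(),
                 mode = character(), stringsAsFactors = FALSE)
    list(loci = loci, pairs = truth[c("gene_a", "gene_b")], truth = truth)
  })
}

#' Generate an FPKM table with planted up/down candidate genes
#'
#' Baseline per-gene abundance is lognormal; planted positive genes are
#' multiplied, and negative genes divided, by `fold` in the two colored
#' varieties (RF and PF) at the selected stages; lognormal replicate noise
#' of sd `noise_sigma` (log scale) is applied throughout. The design
#' mirrors three varieties x two floral stages with `replicates` samples
#' each.
#'
#' @param n_genes total genes.
#' @param n_planted_pos,n_planted_neg planted positive/negative candidates.
#' @param fold linear effect size (>= 2).
#' @param noise_sigma replicate noise sd on the log scale.
#' @param replicates samples per variety/stage.
#' @param seed RNG seed.
#' @param stages stages that receive the planted effect.
#' @return list with `table` (an `expression_table`) and `truth`
#'   (list of `positive` and `negative` gene ids).
#' @export
gen_fpkm_table <- function(n_genes = 100L, n_planted_pos = 10L,
                           n_planted_neg = 10L, fold = 8, noise_sigma = 0.25,
                           replicates = 3L, seed = 1L,
                           stages = c("bud", "full_bloom")) {
  stopifnot(fold >= 2, n_planted_pos + n_planted_neg <= n_genes)
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    planted <- sample(genes, n_planted_pos + n_planted_neg)
    pos <- sort(head(planted, n_planted_pos))
    neg <- sort(planted[seq_len(n_planted_neg) + n_planted_pos])
    base <- rlnorm(n_genes, meanlog = 3, sdlog = 1)
    names(base) <- genes
    meta <- expand.grid(rep = seq_len(replicates),
                        stage = c("bud", "full_bloom"),
                        variety = c("WF", "RF", "PF"),
                        stringsAsFactors = FALSE)
    meta <- data.frame(sample = sprintf("%s_%s_r%d", meta$variety, meta$stage,
                                        meta$rep),
                       variety = meta$variety, stage = meta$stage,
                       stringsAsFactors = FALSE)
    vals <- sapply(seq_len(nrow(meta)), function(j) {
      eff <- rep(1, n_genes)
      if (meta$variety[j] %in% c("RF", "PF") && meta$stage[j] %in% stages) {
        eff[genes %in% pos] <- fold
        eff[genes %in% neg] <- 1 / fold
      }
      base * eff * rlnorm(n_genes, 0, noise_sigma)
    })
    colnames(vals) <- meta$sample
    rownames(vals) <- genes
    list(table = expression_table(vals, meta),
         truth = list(positive = pos, negative = neg))
  })
}
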