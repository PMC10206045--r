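# Duplication-mode typing. Homologous pairs are partitioned into WGD
# (anchors of collinear blocks), tandem (rank-adjacent on one chromosome),
# proximal (within a small rank gap), transposed (exactly one side carries
# collinear evidence) and dispersed (everything else). Block detection is a
# simplified greedy anchor chaining over gene ranks.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Detect collinear blocks by greedy anchor chaining
#'
#' Pairs are oriented per chromosome pair and sorted by rank on side A;
#' a chain is extended while both rank gaps are within `max_rank_gap` and
#' the side-B ranks progress strictly monotonically in a consistent
#' direction. Chains with fewer than `min_anchors` anchors are discarded.
#'
#' @param pairs data.frame gene_a, gene_b (see [read_homolog_pairs()]).
#' @param loci gene table with ranks (see [read_gene_table()]).
#' @param min_anchors minimum anchors per retained block.
#' @param max_rank_gap maximum rank gap between consecutive anchors.
#' @return list of blocks; each block is a list with chrom_a, chrom_b,
#'   n_anchors and anchors (data.frame gene_a, gene_b, rank_a, rank_b).
#' @export
detect_collinear_blocks <- function(pairs, loci, min_anchors = 5L,
                                    max_rank_gap = 25L) {
  if (!nrow(pairs)) return(list())
  absent <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), loci$gene_id)
  if (length(absent)) {
    stopf("pair gene(s) absent from the gene table: %s",
          paste(absent, collapse = ", "))
  }
  ia <- match(pairs$gene_a, loci$gene_id)
  ib <- match(pairs$gene_b, loci$gene_id)
  p <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                  chrom_a = loci$chrom[ia], rank_a = loci$rank[ia],
                  chrom_b = loci$chrom[ib], rank_b = loci$rank[ib],
                  stringsAsFactors = FALSE)
  flip <- p$chrom_a > p$chrom_b |
    (p$chrom_a == p$chrom_b & p$rank_a > p$rank_b)
  p[flip, c("gene_a", "gene_b", "chrom_a", "rank_a", "chrom_b", "rank_b")] <-
    p[flip, c("gene_b", "gene_a", "chrom_b", "rank_b", "chrom_a", "rank_a")]
  blocks <- list()
  for (grp in split(p, paste(p$chrom_a, p$chrom_b, sep = "\r"))) {
    grp <- grp[order(grp$rank_a, grp$rank_b), , drop = FALSE]
    chain <- grp[1, , drop = FALSE]
    dir <- 0L
    flush <- function(chain) {
      if (nrow(chain) >= min_anchors) {
        blocks[[length(blocks) + 1L]] <<- list(
          chrom_a = chain$chrom_a[1], chrom_b = chain$chrom_b[1],
          n_anchors = nrow(chain),
          anchors = chain[c("gene_a", "gene_b", "rank_a", "rank_b")])
      }
    }
    if (nrow(grp) > 1) {
      for (i in 2:nrow(grp)) {
        last <- chain[nrow(chain), ]
        ga <- grp$rank_a[i] - last$rank_a
        gb <- grp$rank_b[i] - last$rank_b
        ok <- ga >= 1L && ga <= max_rank_gap && abs(gb) >= 1L &&
          abs(gb) <= max_rank_gap && (dir == 0L || sign(gb) == dir)
        if (ok) {
          if (dir == 0L) dir <- sign(gb)
          chain <- rbind(chain, grp[i, , drop = FALSE])
        } else {
          flush(chain)
          chain <- grp[i, , drop = FALSE]
          dir <- 0L
        }
      }
    }
    flush(chain)
  }
  blocks
}

block_anchor_keys <- function(blocks) {
  unlist(lapply(blocks, function(b) pair_key(b$anchors$gene_a,
                                             b$anchors$gene_b)))
}

block_anchor_genes <- function(blocks) {
  unique(unlist(lapply(blocks, function(b)
    c(b$anchors$gene_a, b$anchors$gene_b))))
}

#' Classify homologous pairs into the five duplication modes
#'
#' First rule that fires wins: (1) the pair is a block anchor: WGD;
#' (2) same chromosome at rank distance 1: TANDEM; (3) same chromosome at
#' rank distance up to `proximal_max`: PROXIMAL; (4) exactly one gene of
#' the pair occurs among block anchors: TRANSPOSED; (5) otherwise
#' DISPERSED.
#'
#' @param pairs data.frame gene_a, gene_b.
#' @param blocks result of [detect_collinear_blocks()] over the same pairs.
#' @param loci gene table with ranks.
#' @param proximal_max maximum rank gap for a proximal call.
#' @return `pairs` with an added `mode` column.
#' @export
classify_pairs <- function(pairs, blocks, loci, proximal_max = 10L) {
  if (!nrow(pairs)) return(cbind(pairs, mode = character(0)))
  absent <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), loci$gene_id)
  if (length(absent)) {
    stopf("pair gene(s) absent from the gene table: %s",
          paste(absent, collapse = ", "))
  }
  keys <- block_anchor_keys(blocks)
  agenes <- block_anchor_genes(blocks)
  ia <- match(pairs$gene_a, loci$gene_id)
  ib <- match(pairs$gene_b, loci$gene_id)
  same_chr <- loci$chrom[ia] == loci$chrom[ib]
  gap <- abs(loci$rank[ia] - loci$rank[ib])
  in_block <- pair_key(pairs$gene_a, pairs$gene_b) %in% keys
  n_anchor_sides <- (pairs$gene_a %in% agenes) + (pairs$gene_b %in% agenes)
  mode <- ifelse(in_block, "WGD",
          ifelse(same_chr & gap == 1L, "TANDEM",
          ifelse(same_chr & gap <= proximal_max, "PROXIMAL",
          ifelse(n_anchor_sides == 1L, "TRANSPOSED", "DISPERSED"))))
  pairs$mode <- mode
  pairs
}

#' Collapse pair modes to one mode per gene
#'
#' A gene takes the highest-priority mode among its pairs, priority
#' WGD > TANDEM > PROXIMAL > TRANSPOSED > DISPERSED. Genes appearing in no
#' pair are omitted.
#'
#' @param calls data.frame from [classify_pairs()] (gene_a, gene_b, mode).
#' @return data.frame gene_id, mode, n_pairs.
#' @export
assign_gene_modes <- function(calls) {
  if (!nrow(calls)) {
    return(data.frame(gene_id = character(), mode = character(),
                      n_pairs = integer(), stringsAsFactors = FALSE))
  }
  long <- data.frame(gene_id = c(calls$gene_a, calls$gene_b),
                     mode = rep(calls$mode, 2), stringsAsFactors = FALSE)
  long$prio <- match(long$mode, DUP_MODES)
  out <- do.call(rbind, lapply(split(long, long$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], mode = DUP_MODES[min(g$prio)],
               n_pairs = nrow(g), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' One-call duplication-mode analysis
#'
#' @inheritParams detect_collinear_blocks
#' @inheritParams classify_pairs
#' @return list with `blocks`, `pair_modes` and `gene_modes`.
#' @export
dup_mode_analysis <- function(pairs, loci, min_anchors = 5L,
                              max_rank_gap = 25L, proximal_max = 10L) {
  blocks <- detect_collinear_blocks(pairs, loci, min_anchors, max_rank_gap)
  pm <- classify_pairs(pairs, blocks, loci, proximal_max)
  list(blocks = blocks, pair_modes = pm, gene_modes = assign_gene_modes(pm))
}
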