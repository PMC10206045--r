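# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive results from first principles (exhaustive
# enumeration, plain loops) rather than calling the package's internals.

GC <- Biostrings::GENETIC_CODE
NT <- c("A", "C", "G", "T")

# --- zinc-finger grammar oracle -------------------------------------------
# enumerate every placement of C-x{cc}-C-x{s2}-H-x-(H|C), then apply the
# left-to-right, shortest-spacer, non-overlapping acceptance policy
oracle_zinc_fingers <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  placements <- data.frame()
  for (c1 in seq_len(n)) {
    if (ch[c1] != "C") next
    for (geom in list(c(4, "C2H2"), c(5, "C2H2"), c(7, "C2HC"))) {
      cc <- as.integer(geom[1]); type <- geom[2]
      for (s2 in 22:24) {
        c2 <- c1 + cc + 1; h1 <- c2 + s2 + 1; last <- h1 + 2
        if (last > n) next
        tail_res <- if (type == "C2H2") "H" else "C"
        if (ch[c2] == "C" && ch[h1] == "H" && ch[last] == tail_res) {
          placements <- rbind(placements, data.frame(
            zf_type = type, c1 = c1, c2 = c2, h1 = h1, last = last,
            cc_spacer = cc, stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (!nrow(placements)) return(placements)
  placements <- placements[order(placements$c1, placements$cc_spacer,
                                 placements$h1), ]
  accepted <- placements[0, ]
  cursor <- 0
  for (i in seq_len(nrow(placements))) {
    if (placements$c1[i] > cursor) {
      accepted <- rbind(accepted, placements[i, ])
      cursor <- placements$last[i]
    }
  }
  rownames(accepted) <- NULL
  accepted
}

# --- NG86 counting oracle -------------------------------------------------
oracle_syn_fraction <- function(codon) {
  aa <- GC[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in NT) {
      if (nt == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (GC[[alt]] == aa) s <- s + 1 / 3
    }
  }
  s
}

oracle_paths <- function(from, to) {
  # all orderings of the differing positions, as full substitution paths
  dp <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (!length(dp)) return(list(integer(0)))
  if (length(dp) == 1) return(list(dp))
  out <- list()
  for (i in seq_along(dp)) {
    for (rest in oracle_paths({x <- from; substr(x, dp[i], dp[i]) <-
                                 substr(to, dp[i], dp[i]); x}, to)) {
      out[[length(out) + 1]] <- c(dp[i], rest)
    }
  }
  out
}

oracle_ng86 <- function(codons1, codons2) {
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (i in seq_along(codons1)) {
    a <- codons1[i]; b <- codons2[i]
    sds <- c(); nds <- c()
    for (path in oracle_paths(a, b)) {
      cur <- a; sd <- 0; nd <- 0; ok <- TRUE
      for (pos in path) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(b, pos, pos)
        if (GC[[nxt]] == "*") { ok <- FALSE; break }
        if (GC[[cur]] == GC[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
    }
    if (!length(sds)) next  # all pathways pass through stops: codon skipped
    si <- (oracle_syn_fraction(a) + oracle_syn_fraction(b)) / 2
    S <- S + si; N <- N + 3 - si
    Sd <- Sd + mean(sds); Nd <- Nd + mean(nds)
    used <- used + 1
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd, n_codons = used)
}

random_codons <- function(n) {
  nonstop <- names(GC)[GC != "*"]
  sample(nonstop, n, replace = TRUE)
}

# --- duplication-mode rule oracle -----------------------------------------
oracle_pair_mode <- function(gene_a, gene_b, blocks, loci, proximal_max = 10) {
  anchor_pairs <- character(0); anchor_genes <- character(0)
  for (b in blocks) {
    anchor_pairs <- c(anchor_pairs,
                      paste(pmin(b$anchors$gene_a, b$anchors$gene_b),
                            pmax(b$anchors$gene_a, b$anchors$gene_b)))
    anchor_genes <- c(anchor_genes, b$anchors$gene_a, b$anchors$gene_b)
  }
  key <- paste(min(gene_a, gene_b), max(gene_a, gene_b))
  la <- loci[loci$gene_id == gene_a, ]; lb <- loci[loci$gene_id == gene_b, ]
  if (key %in% anchor_pairs) return("WGD")
  if (la$chrom == lb$chrom && abs(la$rank - lb$rank) == 1) return("TANDEM")
  if (la$chrom == lb$chrom && abs(la$rank - lb$rank) <= proximal_max)
    return("PROXIMAL")
  if (sum(c(gene_a, gene_b) %in% anchor_genes) == 1) return("TRANSPOSED")
  "DISPERSED"
}

# --- hypergeometric enrichment oracle -------------------------------------
oracle_hyper_upper <- function(k, K, N, n) {
  # P(X >= k) by direct summation of the probability masses
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
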