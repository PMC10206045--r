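# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction. Synonymous site
# fractions are computed by enumerating each codon's nine single-nucleotide
# neighbors; substitutions between codons differing at 2-3 positions are
# averaged over all orderings of single steps, excluding pathways through
# stop codons. Changes that create a stop codon count as nonsynonymous in
# the site tally so that S + N = 3 x compared codons exactly.

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE
NUCS <- c("A", "C", "G", "T")

.kaks_cache <- new.env(parent = emptyenv())

codon_aa <- function(codon) unname(GENETIC_CODE_TABLE[codon])

is_stop <- function(codon) codon_aa(codon) == "*"

# fraction of the codon's 3 sites that are synonymous (neighbor enumeration)
syn_sites_codon <- function(codon) {
  key <- paste0("S_", codon)
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])
  aa <- codon_aa(codon)
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, ch[pos])) {
      alt <- ch; alt[pos] <- nt
      alt_aa <- codon_aa(paste(alt, collapse = ""))
      if (alt_aa == aa) s <- s + 1 / 3  # stops count as nonsynonymous
    }
  }
  .kaks_cache[[key]] <- s
  s
}

# averaged synonymous/nonsynonymous differences between two codons over all
# stop-free orderings of the single-nucleotide steps; NULL if none exists
codon_differences <- function(c1, c2) {
  key <- paste0("D_", c1, c2)
  if (!is.null(.kaks_cache[[key]])) return(.kaks_cache[[key]])
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diff_pos <- which(a != b)
  res <- if (!length(diff_pos)) {
    c(sd = 0, nd = 0)
  } else {
    perms <- permutations_of(diff_pos)
    sds <- numeric(); nds <- numeric()
    for (ord in perms) {
      cur <- a; sd <- 0; nd <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b[pos]
        from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
        if (is_stop(to)) { ok <- FALSE; break }  # no stops anywhere en route
        if (codon_aa(from) == codon_aa(to)) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) { sds <- c(sds, sd); nds <- c(nds, nd) }
    }
    if (!length(sds)) NULL else c(sd = mean(sds), nd = mean(nds))
  }
  .kaks_cache[[key]] <- res
  res
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

split_codons <- function(seq) {
  if (nchar(seq) %% 3 != 0) stopf("sequence length %d is not a codon multiple",
                                  nchar(seq))
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Build a validated codon alignment from two gapped codon sequences
#'
#' @param seq1,seq2 aligned codon strings of equal length (multiple of 3);
#'   gaps only in whole-codon `---` units; no internal stop codons.
#' @param id optional alignment identifier.
#' @return object of class `codon_alignment`.
#' @export
codon_alignment <- function(seq1, seq2, id = NULL) {
  if (nchar(seq1) != nchar(seq2)) stopf("aligned sequences differ in length")
  rows <- list(split_codons(toupper(seq1)), split_codons(toupper(seq2)))
  for (r in rows) {
    mixed <- grepl("-", r) & r != "---"
    if (any(mixed)) stopf("gap not in whole-codon units at codon %d",
                          which(mixed)[1])
    ungapped <- r[r != "---"]
    stops <- which(vapply(ungapped, is_stop, logical(1)))
    if (length(stops)) stopf("internal stop codon at codon index %d", stops[1])
  }
  structure(list(codons1 = rows[[1]], codons2 = rows[[2]], id = id),
            class = "codon_alignment")
}

#' Back-translate a pairwise protein alignment to a codon alignment
#'
#' Each aligned residue is replaced by its codon from the matching CDS;
#' each protein gap becomes `---`. The ungapped protein must equal the
#' translation of its CDS under the standard genetic code (a terminal stop
#' codon on the CDS is stripped).
#'
#' @param protein_aln named character vector of two gapped protein strings.
#' @param cds named character vector of DNA sequences covering the same ids.
#' @return a `codon_alignment`.
#' @export
backtranslate <- function(protein_aln, cds) {
  stopifnot(length(protein_aln) == 2)
  ids <- names(protein_aln)
  missing <- setdiff(ids, names(cds))
  if (length(missing)) stopf("CDS missing for: %s", paste(missing, collapse = ", "))
  rows <- lapply(ids, function(id) {
    prot <- toupper(protein_aln[[id]])
    dna <- toupper(cds[[id]])
    codons <- split_codons(dna)
    if (length(codons) && is_stop(codons[length(codons)])) {
      wrky_log("stripping terminal stop codon from ", id)
      codons <- codons[-length(codons)]
    }
    stops <- which(vapply(codons, is_stop, logical(1)))
    if (length(stops)) stopf("internal stop codon in %s at codon index %d",
                             id, stops[1])
    res <- strsplit(gsub("-", "", prot), "")[[1]]
    if (length(codons) != length(res)) {
      stopf("CDS length of %s (%d codons) does not match protein (%d aa)",
            id, length(codons), length(res))
    }
    trans <- vapply(codons, codon_aa, character(1))
    bad <- which(trans != res)
    if (length(bad)) {
      stopf("translation mismatch for %s at residue %d (%s vs %s)",
            id, bad[1], trans[bad[1]], res[bad[1]])
    }
    out <- character(nchar(prot))
    k <- 0L
    for (i in seq_len(nchar(prot))) {
      if (substr(prot, i, i) == "-") out[i] <- "---"
      else { k <- k + 1L; out[i] <- codons[k] }
    }
    paste(out, collapse = "")
  })
  codon_alignment(rows[[1]], rows[[2]], id = paste(ids, collapse = "-"))
}

jc_correct <- function(p) {
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori Ka/Ks for a codon alignment
#'
#' Counts average synonymous/nonsynonymous sites over both sequences,
#' averages substitution counts over all stop-free pathways for multi-hit
#' codons (codons whose pathways all pass through stops are skipped), and
#' applies the Jukes-Cantor correction to the proportions. The ratio is
#' undefined when Ks is 0 or a correction is inapplicable (proportion at or
#' above 3/4).
#'
#' @param aln a `codon_alignment`.
#' @param epsilon half-width of the neutral band passed to
#'   [selection_category()].
#' @return object of class `kaks_result`: list with S, N, Sd, Nd, Ka, Ks,
#'   ratio, category, n_codons (compared) and n_skipped.
#' @export
ng86_pair <- function(aln, epsilon = 0.05) {
  stopifnot(inherits(aln, "codon_alignment"))
  keep <- aln$codons1 != "---" & aln$codons2 != "---"
  c1 <- aln$codons1[keep]; c2 <- aln$codons2[keep]
  if (!length(c1)) stopf("no shared ungapped codon columns")
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0L; skipped <- 0L
  for (i in seq_along(c1)) {
    d <- codon_differences(c1[i], c2[i])
    if (is.null(d)) {
      skipped <- skipped + 1L
      wrky_log("codon ", i, " skipped: all pathways pass through stops")
      next
    }
    s_i <- (syn_sites_codon(c1[i]) + syn_sites_codon(c2[i])) / 2
    S <- S + s_i
    N <- N + (3 - s_i)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
    used <- used + 1L
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc_correct(ps)
  Ka <- jc_correct(pn)
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = unname(Sd), Nd = unname(Nd),
                 Ka = Ka, Ks = Ks, ratio = ratio,
                 category = selection_category(ratio, epsilon),
                 n_codons = used, n_skipped = skipped),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("kaks_result: Ka=%.4g Ks=%.4g Ka/Ks=%s (%s; %d codons)\n",
              x$Ka, x$Ks,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4g", x$ratio),
              x$category, x$n_codons))
  invisible(x)
}

#' Selection category from a Ka/Ks ratio
#'
#' Purifying below `1 - epsilon`, positive above `1 + epsilon`, neutral in
#' between; an undefined ratio passes through as `"undefined"`.
#'
#' @param ratio Ka/Ks value or `NA`.
#' @param epsilon half-width of the neutral band around 1.
#' @return one of "purifying", "neutral", "positive", "undefined".
#' @export
selection_category <- function(ratio, epsilon = 0.05) {
  if (is.na(ratio)) return("undefined")
  if (ratio < 0) stopf("negative Ka/Ks ratio")
  if (abs(ratio - 1) <= epsilon) "neutral"
  else if (ratio < 1) "purifying"
  else "positive"
}

#' Ka/Ks for a table of duplicate pairs
#'
#' @param pairs data.frame gene_a, gene_b.
#' @param alignments named list of `codon_alignment`s keyed
#'   `"<gene_a>-<gene_b>"`, or a function(gene_a, gene_b) returning one.
#' @param epsilon neutral band half-width.
#' @return data.frame: gene_a, gene_b, S, N, Sd, Nd, Ka, Ks, ratio, category.
#' @export
kaks_table <- function(pairs, alignments, epsilon = 0.05) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    aln <- if (is.function(alignments)) alignments(a, b)
           else alignments[[paste(a, b, sep = "-")]]
    if (is.null(aln)) stopf("no alignment for pair %s-%s", a, b)
    r <- ng86_pair(aln, epsilon)
    data.frame(gene_a = a, gene_b = b, S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
               Ka = r$Ka, Ks = r$Ks, ratio = r$ratio, category = r$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
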