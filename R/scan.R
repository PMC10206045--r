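# WRKY domain detection: the family's DNA-binding domain is ~60 aa long and
# consists of a conserved heptapeptide (canonically WRKYGQK) followed by a
# zinc finger, either C2H2 (C-X4-5-C-X22-24-H-X-H) or C2HC
# (C-X7-C-X22-24-H-X-C). The scanner finds zinc fingers first, then uses
# them to anchor the (possibly degenerate) heptapeptide search.

CANONICAL_HEPTA <- "WRKYGQK"
ZF_CC_SPACERS <- list(C2H2 = c(4L, 5L), C2HC = 7L)
ZF_CH_SPACERS <- 22:24
HEPTA_PAIR_WINDOW <- 60L   # max aa between heptapeptide start and zf c1
POST_C2_WINDOW <- 12L

check_protein <- function(seq) {
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", seq)) {
    stopf("non-protein characters in sequence")
  }
  invisible(seq)
}

#' Scan a protein for C2H2 and C2HC zinc-finger motifs
#'
#' Matches the grammars C-X4-5-C-X22-24-H-X-H (C2H2) and
#' C-X7-C-X22-24-H-X-C (C2HC). Scanning is left to right and
#' non-overlapping; at equal start the shortest Cys-Cys spacer, then the
#' shortest Cys-His spacer, wins. The 12 residues following the second
#' cysteine are recorded (`post_c2_window`, `-`-padded near the sequence
#' end) because subgroup signature motifs live there.
#'
#' @param seq protein sequence string.
#' @return data.frame with one row per hit: zf_type, c1, c2, h1, last,
#'   cc_spacer, post_c2_window (1-based positions).
#' @export
scan_zinc_fingers <- function(seq) {
  check_protein(seq)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hits <- list()
  i <- 1L
  # candidate geometries in preference order: shortest cc spacer first
  geoms <- rbind(
    expand.grid(cc = 4L, s2 = ZF_CH_SPACERS, type = "C2H2"),
    expand.grid(cc = 5L, s2 = ZF_CH_SPACERS, type = "C2H2"),
    expand.grid(cc = 7L, s2 = ZF_CH_SPACERS, type = "C2HC")
  )
  while (i <= n) {
    if (ch[i] != "C") { i <- i + 1L; next }
    found <- NULL
    for (g in seq_len(nrow(geoms))) {
      cc <- geoms$cc[g]; s2 <- geoms$s2[g]; type <- as.character(geoms$type[g])
      c2 <- i + cc + 1L
      h1 <- c2 + s2 + 1L
      last <- h1 + 2L
      if (last > n) next
      tail_res <- if (type == "C2H2") "H" else "C"
      if (ch[c2] == "C" && ch[h1] == "H" && ch[last] == tail_res) {
        found <- list(type = type, c1 = i, c2 = c2, h1 = h1, last = last,
                      cc = cc)
        break
      }
    }
    if (is.null(found)) { i <- i + 1L; next }
    win <- ch[seq(found$c2 + 1L, min(found$c2 + POST_C2_WINDOW, n))]
    win <- paste0(paste(win, collapse = ""),
                  strrep("-", POST_C2_WINDOW - length(win)))
    hits[[length(hits) + 1L]] <- data.frame(
      zf_type = found$type, c1 = found$c1, c2 = found$c2, h1 = found$h1,
      last = found$last, cc_spacer = found$cc, post_c2_window = win,
      stringsAsFactors = FALSE)
    i <- found$last + 1L
  }
  if (!length(hits)) {
    return(data.frame(zf_type = character(), c1 = integer(), c2 = integer(),
                      h1 = integer(), last = integer(), cc_spacer = integer(),
                      post_c2_window = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Scan a protein for WRKYGQK heptapeptides, including degenerate variants
#'
#' All exact WRKYGQK occurrences are reported. In addition, for each
#' zinc-finger anchor the best WR-prefixed 7-mer within the 60 residues
#' upstream with at most 4 mismatches to WRKYGQK is reported (this admits
#' natural variants such as WRKYGEK, WRKYGRK and WRQCRRK); ties go to the
#' candidate closest to the anchor. A terminal WR/WRK prefix that cannot be
#' completed before the sequence ends is reported as a partial hit.
#'
#' @param seq protein sequence string.
#' @param anchors zinc-finger hits from [scan_zinc_fingers()] on the same
#'   sequence (may have zero rows).
#' @return data.frame: start, motif7, mismatches, partial; sorted by start.
#' @export
scan_heptapeptides <- function(seq, anchors = NULL) {
  check_protein(seq)
  n <- nchar(seq)
  canon <- strsplit(CANONICAL_HEPTA, "")[[1]]
  hits <- list()
  add <- function(start, motif7, mismatches, partial) {
    hits[[length(hits) + 1L]] <<- data.frame(
      start = start, motif7 = motif7, mismatches = mismatches,
      partial = partial, stringsAsFactors = FALSE)
  }
  exact <- gregexpr(CANONICAL_HEPTA, seq, fixed = TRUE)[[1]]
  if (exact[1] != -1) {
    for (p in as.integer(exact)) add(p, CANONICAL_HEPTA, 0L, FALSE)
  }
  mism_at <- function(p) {
    sum(strsplit(substr(seq, p, p + 6L), "")[[1]] != canon)
  }
  if (!is.null(anchors) && nrow(anchors)) {
    for (a in seq_len(nrow(anchors))) {
      c1 <- anchors$c1[a]
      lo <- max(1L, c1 - HEPTA_PAIR_WINDOW)
      hi <- c1 - 7L
      if (hi < lo) next
      cand <- integer(); mm <- integer()
      for (p in lo:hi) {
        if (substr(seq, p, p + 1L) != "WR") next
        d <- mism_at(p)
        if (d <= 4L) { cand <- c(cand, p); mm <- c(mm, d) }
      }
      if (!length(cand)) next
      best <- cand[mm == min(mm)]
      p <- max(best)  # closest to the anchor
      add(p, substr(seq, p, p + 6L), min(mm), FALSE)
    }
  }
  # truncated terminal motif: a WR/WRK prefix with no room to complete
  for (k in c(3L, 2L)) {
    p <- n - k + 1L
    if (p >= 1L && substr(seq, p, n) == substr(CANONICAL_HEPTA, 1L, k)) {
      add(p, substr(seq, p, n), NA_integer_, TRUE)
      break
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), motif7 = character(),
                      mismatches = integer(), partial = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out$start), , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble WRKY domains for one protein
#'
#' Zinc fingers are paired to the nearest upstream heptapeptide within the
#' 60-aa pairing window. Unpaired heptapeptides with at most one mismatch
#' (or truncated partial motifs) are kept as zinc-finger-absent domains. A
#' protein whose annotation is empty is not a WRKY.
#'
#' @param seq protein sequence string.
#' @param protein_id identifier used in the annotation.
#' @return object of class `wrky_annotation`: list with `protein_id`,
#'   `domains` (data.frame sorted by heptapeptide start), `n_complete`
#'   (domains with both motifs intact) and `zf_lost` (any heptapeptide
#'   without a zinc finger).
#' @export
assemble_domains <- function(seq, protein_id = "protein") {
  zfs <- scan_zinc_fingers(seq)
  heptas <- scan_heptapeptides(seq, zfs)
  empty_zf <- list(zf_type = NA_character_, c1 = NA_integer_, c2 = NA_integer_,
                   h1 = NA_integer_, last = NA_integer_,
                   cc_spacer = NA_integer_, post_c2_window = NA_character_)
  used_hepta <- rep(FALSE, nrow(heptas))
  domains <- list()
  if (nrow(zfs)) {
    for (z in seq_len(nrow(zfs))) {
      ok <- which(!used_hepta & !heptas$partial &
                    heptas$start < zfs$c1[z] &
                    zfs$c1[z] - heptas$start <= HEPTA_PAIR_WINDOW)
      if (!length(ok)) next  # orphan zinc finger: not a WRKY domain
      h <- ok[which.max(heptas$start[ok])]
      used_hepta[h] <- TRUE
      domains[[length(domains) + 1L]] <- c(
        list(hepta_start = heptas$start[h], motif7 = heptas$motif7[h],
             mismatches = heptas$mismatches[h], partial = FALSE),
        as.list(zfs[z, , drop = FALSE]),
        list(complete = TRUE))
    }
  }
  for (h in which(!used_hepta)) {
    keep <- isTRUE(heptas$partial[h]) ||
      (!is.na(heptas$mismatches[h]) && heptas$mismatches[h] <= 1L)
    if (!keep) next
    domains[[length(domains) + 1L]] <- c(
      list(hepta_start = heptas$start[h], motif7 = heptas$motif7[h],
           mismatches = heptas$mismatches[h], partial = heptas$partial[h]),
      empty_zf, list(complete = FALSE))
  }
  if (length(domains)) {
    dom <- do.call(rbind, lapply(domains, function(d)
      as.data.frame(d, stringsAsFactors = FALSE)))
    dom <- dom[order(dom$hepta_start), , drop = FALSE]
    rownames(dom) <- NULL
  } else {
    dom <- data.frame(hepta_start = integer(), motif7 = character(),
                      mismatches = integer(), partial = logical(),
                      zf_type = character(), c1 = integer(), c2 = integer(),
                      h1 = integer(), last = integer(), cc_spacer = integer(),
                      post_c2_window = character(), complete = logical(),
                      stringsAsFactors = FALSE)
  }
  structure(list(protein_id = protein_id, domains = dom,
                 n_complete = sum(dom$complete),
                 zf_lost = any(is.na(dom$zf_type))),
            class = "wrky_annotation")
}

#' @export
print.wrky_annotation <- function(x, ...) {
  cat(sprintf("wrky_annotation %s: %d domain(s), %d complete%s\n",
              x$protein_id, nrow(x$domains), x$n_complete,
              if (x$zf_lost) ", zinc finger lost" else ""))
  invisible(x)
}

#' Annotate every WRKY protein in a proteome
#'
#' Proteins with no detected WRKY domain are dropped (the family retention
#' rule: only sequences with at least one WRKY signature are kept).
#'
#' @param seqs named character vector of protein sequences.
#' @return named list of `wrky_annotation` objects, WRKY proteins only.
#' @export
annotate_wrky_proteome <- function(seqs) {
  anns <- lapply(names(seqs), function(id) assemble_domains(seqs[[id]], id))
  names(anns) <- names(seqs)
  anns[vapply(anns, function(a) nrow(a$domains) > 0L, logical(1))]
}

#' Flatten annotations to a per-domain table
#'
#' @param annotations list of `wrky_annotation` objects.
#' @return data.frame: protein_id, domain_index, hepta_start, motif7,
#'   mismatches, zf_type, c1, c2, spacer, complete.
#' @export
domain_table <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    if (!nrow(a$domains)) return(NULL)
    data.frame(protein_id = a$protein_id,
               domain_index = seq_len(nrow(a$domains)),
               hepta_start = a$domains$hepta_start,
               motif7 = a$domains$motif7,
               mismatches = a$domains$mismatches,
               zf_type = a$domains$zf_type,
               c1 = a$domains$c1, c2 = a$domains$c2,
               spacer = a$domains$cc_spacer,
               complete = a$domains$complete,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out %||% data.frame()
}
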