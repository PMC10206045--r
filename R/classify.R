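# Group/subgroup assignment. Family rules: Group I has two WRKY domains and
# a C2H2 finger; Group III has one domain with a C2HC finger; Group II has a
# single C2H2 domain and splits into IIa-IIe by the Cys-Cys spacer (CX4C for
# IIc) and by a signature motif immediately after the second cysteine for
# IIa/IIb/IId/IIe. Proteins without a usable zinc finger are UC
# (unclassified) and are resolved by label transfer on a phylogeny.

# subgroup signature grammars on the post-c2 window, anchored at position 1
SUBGROUP_SIGNATURES <- list(
  IIa = c("PVKKKLQ", "PVKKKVQ"),
  IIb = "PVRKQVQ",
  IId = "PARKHVE",
  IIe = c("PARKQVE", "PARKQVD", "PARKMVE", "PARKMVD")
)

classification_result <- function(protein_id, label, basis, evidence) {
  data.frame(protein_id = protein_id, label = label, basis = basis,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Structurally classify one annotated WRKY protein
#'
#' Decision ladder, first match wins: (1) two or more domains with any C2H2
#' finger: Group I; (2) any C2HC finger: Group III; (3) no zinc finger on
#' any domain, or only partial heptapeptides: UC; (4) single C2H2 domain
#' with a 4-residue Cys-Cys spacer: IIc; (5) single C2H2 with a 5-residue
#' spacer: signature match (exact, then minimum Hamming distance up to
#' `max_mismatch`) decides IIa/IIb/IId/IIe, otherwise UC.
#'
#' @param annotation a `wrky_annotation` with at least one domain.
#' @param max_mismatch Hamming tolerance for degraded subgroup signatures.
#' @return one-row data.frame: protein_id, label, basis, evidence.
#' @export
classify_structural <- function(annotation, max_mismatch = 2L) {
  stopifnot(inherits(annotation, "wrky_annotation"))
  dom <- annotation$domains
  if (!nrow(dom)) stopf("%s has no WRKY domain: not a WRKY protein",
                        annotation$protein_id)
  id <- annotation$protein_id
  has_c2h2 <- any(dom$zf_type == "C2H2", na.rm = TRUE)
  has_c2hc <- any(dom$zf_type == "C2HC", na.rm = TRUE)
  if (nrow(dom) >= 2L && has_c2h2) {
    return(classification_result(id, "I", "structural",
                                 sprintf("%d domains, C2H2", nrow(dom))))
  }
  if (has_c2hc) {
    return(classification_result(id, "III", "structural", "C2HC zinc finger"))
  }
  if (!has_c2h2 || all(dom$partial)) {
    return(classification_result(id, "UC", "structural",
                                 "zinc finger lost or motif partial"))
  }
  zf <- dom[which(dom$zf_type == "C2H2")[1], ]
  if (zf$cc_spacer == 4L) {
    return(classification_result(id, "IIc", "structural", "CX4C spacer"))
  }
  win <- zf$post_c2_window
  for (sg in names(SUBGROUP_SIGNATURES)) {
    for (sig in SUBGROUP_SIGNATURES[[sg]]) {
      if (substr(win, 1L, nchar(sig)) == sig) {
        return(classification_result(id, sg, "structural",
                                     sprintf("signature %s", sig)))
      }
    }
  }
  # degraded signature: nearest by Hamming distance, subgroups tie-broken
  # lexically for determinism
  best_sg <- NA_character_; best_d <- Inf; best_sig <- NA_character_
  for (sg in names(SUBGROUP_SIGNATURES)) {
    for (sig in SUBGROUP_SIGNATURES[[sg]]) {
      d <- hamming(substr(win, 1L, nchar(sig)), sig)
      if (d < best_d || (d == best_d && sg < best_sg)) {
        best_d <- d; best_sg <- sg; best_sig <- sig
      }
    }
  }
  if (best_d <= max_mismatch) {
    return(classification_result(id, best_sg, "structural",
                                 sprintf("signature %s at Hamming %d",
                                         best_sig, best_d)))
  }
  classification_result(id, "UC", "structural", "no subgroup signature")
}

#' Structurally classify a list of annotated proteins
#'
#' @param annotations list of `wrky_annotation` objects (see
#'   [annotate_wrky_proteome()]).
#' @param max_mismatch passed to [classify_structural()].
#' @return data.frame with one row per protein.
#' @export
classify_proteins <- function(annotations, max_mismatch = 2L) {
  out <- do.call(rbind, lapply(annotations, classify_structural,
                               max_mismatch = max_mismatch))
  rownames(out) <- NULL
  out
}

#' Resolve UC proteins by nearest-labeled-leaf transfer on a phylogeny
#'
#' Each structurally UC protein must be a leaf of the tree; it receives the
#' label of the nearest labeled leaf by patristic distance. Ties are broken
#' by the majority label among the tied leaves, then by the lexically
#' smallest label. Labeled leaves are the tree's own label map plus any
#' structurally classified (non-UC) proteins present in the tree;
#' structurally classified labels are never changed.
#'
#' @param ltree a `labeled_tree` from [read_newick()].
#' @param structural classification data.frame from [classify_proteins()].
#' @return the classification data.frame with UC rows resolved
#'   (basis `"tree"` where a transfer occurred).
#' @export
transfer_labels <- function(ltree, structural) {
  stopifnot(inherits(ltree, "labeled_tree"))
  tree <- ltree$tree
  labels <- ltree$labels
  known <- structural$label[match(names(labels), structural$protein_id)]
  use <- labels == "UC" & !is.na(known) & known != "UC"
  labels[use] <- known[use]
  uc_ids <- structural$protein_id[structural$label == "UC"]
  if (!length(uc_ids)) return(structural)
  missing <- setdiff(uc_ids, tree$tip.label)
  if (length(missing)) {
    stopf("unclassified protein(s) missing from the tree: %s",
          paste(missing, collapse = ", "))
  }
  labeled_leaves <- names(labels)[labels != "UC"]
  if (!length(labeled_leaves)) stopf("tree has no labeled leaves")
  dmat <- ape::cophenetic.phylo(tree)
  for (id in uc_ids) {
    d <- dmat[id, labeled_leaves]
    tied <- labeled_leaves[d <= min(d) + 1e-12]
    cand <- table(labels[tied])
    winners <- names(cand)[cand == max(cand)]
    lab <- sort(winners)[1]
    i <- which(structural$protein_id == id)
    structural$label[i] <- lab
    structural$basis[i] <- "tree"
    structural$evidence[i] <- sprintf(
      "nearest labeled leaf %s at distance %.4g",
      tied[which(labels[tied] == lab)][1], min(d))
  }
  structural
}

#' Apply a fixed reassignment map to classification results
#'
#' Used to inject published clade-based reassignments of structurally
#' unclassifiable members in place of re-deriving them from a tree.
#'
#' @param results classification data.frame.
#' @param map named character vector, protein id to group label.
#' @return updated data.frame (basis `"fixture"` for remapped rows).
#' @export
apply_reassignment <- function(results, map) {
  stopifnot(all(map %in% GROUP_LABELS))
  unknown <- setdiff(names(map), results$protein_id)
  if (length(unknown)) stopf("reassignment for unknown protein(s): %s",
                             paste(unknown, collapse = ", "))
  i <- match(names(map), results$protein_id)
  results$label[i] <- unname(map)
  results$basis[i] <- "fixture"
  results$evidence[i] <- "published clade reassignment"
  results
}

#' Tally classification results per subgroup and per main group
#'
#' @param results classification data.frame (column `label`) or a character
#'   vector of labels.
#' @return list with `subgroups` (named counts over the closed label
#'   vocabulary), `main` (I, II = IIa+...+IIe, III, UC) and `total`.
#' @export
summarize_groups <- function(results) {
  labels <- if (is.data.frame(results)) results$label else results
  bad <- setdiff(unique(labels), GROUP_LABELS)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  sub <- table(factor(labels, levels = GROUP_LABELS))
  sub <- setNames(as.integer(sub), names(sub))
  main <- c(I = sub[["I"]],
            II = sum(sub[c("IIa", "IIb", "IIc", "IId", "IIe")]),
            III = sub[["III"]],
            UC = sub[["UC"]])
  list(subgroups = sub, main = main, total = length(labels))
}
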