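# Packaged reference data transcribed from the published azalea WRKY
# analysis: the 57-gene family table, the per-stage candidate lists, the
# clade-based reassignment of the four zinc-finger-lost members, and the
# five-species group-count reference. The family table prints the four
# zinc-finger-lost genes under their post-hoc clade labels; their
# structural status ("Lost" zinc finger) is kept in a separate column so
# both readings are available.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "wrkykit")
  if (!nzchar(p)) stopf("packaged fixture %s not found", file)
  p
}

#' Load the packaged azalea WRKY reference fixtures
#'
#' Returns the transcribed family table (57 RsWRKY genes with heptapeptide,
#' zinc-finger type, domain number, duplication type and ortholog), the
#' per-stage candidate gene lists, the reassignment map for the four
#' structurally unclassifiable members, and five-species group counts.
#' Invariants (record counts, closed vocabularies, list sizes) are checked
#' at load time and violations are errors.
#'
#' @return list with `table1` (data.frame), `candidates` (list bud_up,
#'   bud_down, bloom_up, bloom_down), `reassignment` (named character) and
#'   `table2` (data.frame of per-species group counts).
#' @export
load_fixtures <- function() {
  t1 <- read.delim(fixture_path("table1_rswrky.tsv"), stringsAsFactors = FALSE)
  if (nrow(t1) != 57L) stopf("family table must have 57 records, got %d", nrow(t1))
  stopifnot(!anyDuplicated(t1$name), !anyDuplicated(t1$gene_id),
            all(t1$group_printed %in% setdiff(GROUP_LABELS, "UC")),
            all(t1$zf_type %in% c("C2H2", "C2HC", "Lost")),
            all(t1$domain_number %in% c(1L, 2L)),
            all(t1$gene_type %in% c("WGD", "Tandem", "Proximal",
                                    "Transposed", "Dispersed")))
  cl <- read.delim(fixture_path("candidate_lists.tsv"), stringsAsFactors = FALSE)
  candidates <- list(
    bud_up = cl$gene[cl$stage == "bud" & cl$direction == "up"],
    bud_down = cl$gene[cl$stage == "bud" & cl$direction == "down"],
    bloom_up = cl$gene[cl$stage == "full_bloom" & cl$direction == "up"],
    bloom_down = cl$gene[cl$stage == "full_bloom" & cl$direction == "down"])
  sizes <- lengths(candidates)
  if (!identical(unname(sizes), c(4L, 13L, 4L, 5L))) {
    stopf("candidate list sizes %s violate the packaged invariant",
          paste(sizes, collapse = "/"))
  }
  stopifnot(!anyDuplicated(candidates$bud_up), !anyDuplicated(candidates$bud_down),
            !anyDuplicated(candidates$bloom_up), !anyDuplicated(candidates$bloom_down),
            all(unlist(candidates) %in% t1$name))
  rm_df <- read.delim(fixture_path("reassignment_map.tsv"), stringsAsFactors = FALSE)
  reassignment <- setNames(rm_df$group, rm_df$name)
  lost <- t1$name[t1$zf_type == "Lost"]
  if (!setequal(names(reassignment), lost)) {
    stopf("reassignment keys must be exactly the zinc-finger-lost genes")
  }
  t2 <- read.delim(fixture_path("table2_group_counts.tsv"),
                   stringsAsFactors = FALSE)
  stopifnot(nrow(t2) == 5L,
            all(rowSums(t2[, c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III")]) ==
                  t2$total))
  list(table1 = t1, candidates = candidates, reassignment = reassignment,
       table2 = t2)
}

#' Classification summary of the packaged family table
#'
#' Takes the printed group of each gene, resets the four zinc-finger-lost
#' members to UC (their structural status), applies the clade reassignment
#' map, and tallies groups. This reproduces the published group counts
#' from packaged data alone.
#'
#' @param fixtures result of [load_fixtures()] (loaded fresh if omitted).
#' @return list with `summary` (see [summarize_groups()]), `n_lost`
#'   (zinc-finger-lost genes) and `labels` (named per-gene labels).
#' @export
fixture_classification_summary <- function(fixtures = load_fixtures()) {
  t1 <- fixtures$table1
  labels <- setNames(t1$group_printed, t1$name)
  labels[t1$zf_type == "Lost"] <- "UC"
  res <- classification_result(names(labels), unname(labels), "fixture",
                               "printed family table")
  res <- apply_reassignment(res, fixtures$reassignment)
  list(summary = summarize_groups(res),
       n_lost = sum(t1$zf_type == "Lost"),
       labels = setNames(res$label, res$protein_id))
}

#' Duplication-type tally of the packaged family table
#'
#' @param fixtures result of [load_fixtures()].
#' @return named integer counts over the five duplication types, plus the
#'   WGD percentage as attribute `wgd_pct`.
#' @export
fixture_dup_tally <- function(fixtures = load_fixtures()) {
  tal <- table(factor(fixtures$table1$gene_type,
                      levels = c("WGD", "Tandem", "Proximal", "Transposed",
                                 "Dispersed")))
  out <- setNames(as.integer(tal), names(tal))
  attr(out, "wgd_pct") <- 100 * out[["WGD"]] / sum(out)
  out
}

#' Candidate screen on the packaged per-stage DEG lists
#'
#' Rebuilds each stage's two-contrast DEG sets from the packaged lists
#' (both colored-vs-white contrasts print identical intersected lists, so
#' the packaged lists feed both sides) and intersects them.
#'
#' @param fixtures result of [load_fixtures()].
#' @return list with `bud` and `full_bloom` `candidate_result`s and
#'   `both_stages`, the genes present in both stages' candidate sets.
#' @export
fixture_candidate_screen <- function(fixtures = load_fixtures()) {
  cd <- fixtures$candidates
  bud <- screen_candidates(
    deg_set_from_lists(cd$bud_up, cd$bud_down, "WF_vs_RF_bud", "bud"),
    deg_set_from_lists(cd$bud_up, cd$bud_down, "WF_vs_PF_bud", "bud"))
  bloom <- screen_candidates(
    deg_set_from_lists(cd$bloom_up, cd$bloom_down, "WF_vs_RF_bloom",
                       "full_bloom"),
    deg_set_from_lists(cd$bloom_up, cd$bloom_down, "WF_vs_PF_bloom",
                       "full_bloom"))
  list(bud = bud, full_bloom = bloom,
       both_stages = sort(intersect(c(bud$positive, bud$negative),
                                    c(bloom$positive, bloom$negative))))
}
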