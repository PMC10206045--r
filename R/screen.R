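# Candidate-gene screen: FPKM fold-change DEG calling between flower-color
# varieties at one floral stage, intersection of the two colored-vs-white
# contrasts, ddCt qPCR arithmetic, and hypergeometric term enrichment.

#' Define a two-group expression contrast
#'
#' @param name contrast name (e.g. `"WF_vs_RF_bud"`).
#' @param baseline,treatment disjoint non-empty character vectors of sample
#'   ids (baseline is the denominator of the fold change).
#' @param stage floral stage shared by all samples, `"bud"` or
#'   `"full_bloom"`.
#' @return object of class `contrast`.
#' @export
contrast <- function(name, baseline, treatment, stage = c("bud", "full_bloom")) {
  stage <- match.arg(stage)
  stopifnot(length(baseline) > 0, length(treatment) > 0)
  if (length(intersect(baseline, treatment))) {
    stopf("baseline and treatment samples overlap")
  }
  structure(list(name = name, baseline = baseline, treatment = treatment,
                 stage = stage), class = "contrast")
}

#' Per-gene log2 fold change for a contrast
#'
#' `log2((mean treatment FPKM + pseudocount) / (mean baseline FPKM +
#' pseudocount))`; replicate means are arithmetic. The pseudocount keeps
#' all-zero genes at fold change 0.
#'
#' @param table an `expression_table`.
#' @param contrast a [contrast()].
#' @param pseudocount value added to both means before the ratio.
#' @return named numeric vector, one log2 fold change per gene.
#' @export
log2_fold_change <- function(table, contrast, pseudocount = 1.0) {
  stopifnot(inherits(table, "expression_table"), inherits(contrast, "contrast"))
  missing <- setdiff(c(contrast$baseline, contrast$treatment),
                     colnames(table$values))
  if (length(missing)) stopf("sample(s) not in expression table: %s",
                             paste(missing, collapse = ", "))
  mt <- rowMeans(table$values[, contrast$treatment, drop = FALSE])
  mb <- rowMeans(table$values[, contrast$baseline, drop = FALSE])
  log2((mt + pseudocount) / (mb + pseudocount))
}

#' Call differentially expressed genes from log2 fold changes
#'
#' Boundary values are included: up means log2FC >= `threshold`, down means
#' log2FC <= -`threshold` (the |fold change| >= 2 rule at the default).
#'
#' @param fc named numeric vector from [log2_fold_change()].
#' @param threshold positive log2 fold-change cutoff.
#' @param name contrast name carried along.
#' @param stage floral stage carried along.
#' @return object of class `deg_set`: list with `name`, `stage`, `up`,
#'   `down` (character vectors) and `fc`.
#' @export
call_degs <- function(fc, threshold = 1.0, name = "contrast", stage = "bud") {
  stopifnot(threshold > 0)
  structure(list(name = name, stage = stage,
                 up = names(fc)[fc >= threshold],
                 down = names(fc)[fc <= -threshold],
                 fc = fc),
            class = "deg_set")
}

#' Build a DEG set directly from an expression table and contrast
#'
#' @inheritParams log2_fold_change
#' @inheritParams call_degs
#' @return a `deg_set`.
#' @export
degs_for_contrast <- function(table, contrast, threshold = 1.0,
                              pseudocount = 1.0) {
  fc <- log2_fold_change(table, contrast, pseudocount)
  call_degs(fc, threshold, name = contrast$name, stage = contrast$stage)
}

#' Construct a DEG set from explicit up/down gene lists
#'
#' For published DEG lists where the underlying fold changes are not
#' available.
#'
#' @param up,down character vectors of gene ids.
#' @param name,stage carried along.
#' @return a `deg_set` (with an empty `fc` map).
#' @export
deg_set_from_lists <- function(up, down, name = "contrast", stage = "bud") {
  if (length(intersect(up, down))) stopf("up and down sets overlap")
  structure(list(name = name, stage = stage, up = unique(up),
                 down = unique(down), fc = numeric(0)),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set %s (%s): %d up, %d down\n", x$name, x$stage,
              length(x$up), length(x$down)))
  invisible(x)
}

#' Intersect two colored-versus-white DEG sets into candidate regulators
#'
#' Positive candidates (putative anthocyanin promoters) are genes up in
#' both contrasts; negative candidates (putative suppressors) are genes
#' down in both. Both DEG sets must come from the same floral stage.
#'
#' @param deg_rf,deg_pf `deg_set`s for the two colored-vs-white contrasts.
#' @return object of class `candidate_result`: list with `stage`,
#'   `positive` and `negative` gene vectors.
#' @export
screen_candidates <- function(deg_rf, deg_pf) {
  stopifnot(inherits(deg_rf, "deg_set"), inherits(deg_pf, "deg_set"))
  if (!identical(deg_rf$stage, deg_pf$stage)) {
    stopf("stage mismatch: %s vs %s", deg_rf$stage, deg_pf$stage)
  }
  structure(list(stage = deg_rf$stage,
                 positive = sort(intersect(deg_rf$up, deg_pf$up)),
                 negative = sort(intersect(deg_rf$down, deg_pf$down))),
            class = "candidate_result")
}

#' @export
print.candidate_result <- function(x, ...) {
  cat(sprintf("candidate_result (%s): %d positive, %d negative\n",
              x$stage, length(x$positive), length(x$negative)))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, dCt = Ct(target) - mean(Ct of the reference genes); per
#' group, ddCt = mean dCt(group) - mean dCt(calibrator group); the fold
#' change is 2^-ddCt (identically 1 for the calibrator).
#'
#' @param ct data.frame with columns `sample`, `group`, `target` (target
#'   Ct) and one column per reference gene.
#' @param ref_cols names of the reference-gene Ct columns.
#' @param calibrator group level used as the calibrator.
#' @return named numeric vector of fold changes, one per group.
#' @export
ddct_fold_change <- function(ct, ref_cols, calibrator) {
  need <- c("sample", "group", "target", ref_cols)
  if (!all(need %in% names(ct))) {
    stopf("Ct table missing column(s): %s",
          paste(setdiff(need, names(ct)), collapse = ", "))
  }
  if (!calibrator %in% ct$group) stopf("calibrator group %s absent", calibrator)
  vals <- ct[, c("target", ref_cols), drop = FALSE]
  if (anyNA(vals)) {
    stopf("missing Ct for sample %s", ct$sample[which(rowSums(is.na(vals)) > 0)[1]])
  }
  dct <- ct$target - rowMeans(ct[, ref_cols, drop = FALSE])
  mean_dct <- tapply(dct, ct$group, mean)
  ddct <- mean_dct - mean_dct[[calibrator]]
  fold <- 2^(-ddct)
  setNames(as.numeric(fold), names(ddct))
}

#' Term over-representation by the hypergeometric (Fisher one-sided) test
#'
#' For each term with K population genes and k study hits, p is the upper
#' hypergeometric tail P(X >= k) for a study of size n drawn from a
#' population of size N. Bonferroni correction multiplies by the number of
#' terms actually tested, capped at 1.
#'
#' @param study character vector of study genes (subset of `population`).
#' @param population character vector of background genes.
#' @param term_map data.frame with columns `term` and `gene` (term genes
#'   outside the population are ignored).
#' @param alpha significance level on the corrected p-value.
#' @return data.frame: term, k, n, K, N, p, padj, significant; sorted by p.
#' @export
fisher_enrichment <- function(study, population, term_map, alpha = 0.05) {
  study <- unique(study); population <- unique(population)
  outside <- setdiff(study, population)
  if (length(outside)) stopf("study gene(s) outside the population: %s",
                             paste(outside, collapse = ", "))
  if (!all(c("term", "gene") %in% names(term_map))) {
    stopf("term map must have columns term, gene")
  }
  term_map <- term_map[term_map$gene %in% population, , drop = FALSE]
  term_map <- term_map[!duplicated(term_map[c("term", "gene")]), ]
  N <- length(population); n <- length(study)
  terms <- unique(term_map$term)
  rows <- lapply(terms, function(tm) {
    genes <- term_map$gene[term_map$term == tm]
    K <- length(genes)
    k <- length(intersect(genes, study))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      padj = numeric(), significant = logical()))
  }
  out$padj <- pmin(1, out$p * nrow(out))
  out$significant <- out$padj < alpha
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
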