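#' Read a FASTA file of protein or DNA sequences
#'
#' Sequences are upper-cased and whitespace-stripped; identifiers are the
#' first whitespace-delimited token of each header. Duplicate identifiers,
#' empty sequences and residues outside the declared alphabet (20 amino
#' acids plus X for protein, ACGTN for DNA) are rejected rather than
#' repaired.
#'
#' @param path path to a FASTA file.
#' @param moltype `"protein"` or `"dna"`.
#' @return named character vector of sequences, names are record ids in
#'   file order.
#' @export
read_fasta <- function(path, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  if (anyDuplicated(ids)) {
    stopf("duplicate FASTA id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stopf("empty sequence for id(s): %s",
          paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  pat <- if (moltype == "protein") "^[ACDEFGHIKLMNPQRSTVWYX]+$" else "^[ACGTN]+$"
  bad <- !grepl(pat, seqs)
  if (any(bad)) {
    stopf("sequence(s) with residues outside the %s alphabet: %s",
          moltype, paste(ids[bad], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector as returned by [read_fasta()].
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene-position table and compute chromosome-wise gene ranks
#'
#' Input is a TSV with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (1-based inclusive coordinates, GFF convention). Each gene receives a
#' 0-based `rank`: its ordinal position along its chromosome by ascending
#' start, ties broken by `gene_id`.
#'
#' @param path path to the TSV.
#' @return data.frame with columns gene_id, chrom, start, end, strand, rank.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stopf("gene table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    wrky_log("gene table ", path, " is empty", level = "WARN")
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), rank = integer()))
  }
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stopf("gene table missing column(s): %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  df <- df[need]
  if (anyDuplicated(df$gene_id)) {
    stopf("duplicate gene_id(s): %s",
          paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  bad <- df$start > df$end
  if (any(bad)) stopf("start > end for gene(s): %s",
                      paste(df$gene_id[bad], collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) {
    stopf("unknown strand symbol(s): %s",
          paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  }
  df <- df[order(df$chrom, df$start, df$gene_id), ]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$chrom)[unique(df$chrom)],
                           function(idx) seq_along(idx) - 1L),
                    use.names = FALSE)
  rownames(df) <- NULL
  df
}

compute_ranks <- function(loci) {
  # recompute 0-based per-chromosome ranks for an in-memory gene table
  loci <- loci[order(loci$chrom, loci$start, loci$gene_id), ]
  loci$rank <- unlist(lapply(split(seq_len(nrow(loci)), loci$chrom)[unique(loci$chrom)],
                             function(idx) seq_along(idx) - 1L),
                      use.names = FALSE)
  rownames(loci) <- NULL
  loci
}

#' Read a homologous gene-pair table
#'
#' TSV with columns `gene_a`, `gene_b` and optional `score`. Pairs are
#' unordered and are canonicalized so `gene_a < gene_b` lexically;
#' self-pairs are rejected.
#'
#' @param path path to the TSV.
#' @return data.frame gene_a, gene_b, score.
#' @export
read_homolog_pairs <- function(path) {
  if (!file.exists(path)) stopf("pair table not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    stopf("pair table must have columns gene_a, gene_b")
  }
  if (!"score" %in% names(df)) df$score <- NA_real_
  canonicalize_pairs(df[c("gene_a", "gene_b", "score")])
}

canonicalize_pairs <- function(df) {
  if (nrow(df) == 0) return(df)
  if (any(df$gene_a == df$gene_b)) {
    stopf("self-pair(s): %s",
          paste(df$gene_a[df$gene_a == df$gene_b], collapse = ", "))
  }
  swap <- df$gene_a > df$gene_b
  tmp <- df$gene_a[swap]
  df$gene_a[swap] <- df$gene_b[swap]
  df$gene_b[swap] <- tmp
  df <- df[!duplicated(df[c("gene_a", "gene_b")]), ]
  rownames(df) <- NULL
  df
}

#' Read an FPKM expression matrix with sample metadata
#'
#' The matrix TSV has gene ids in the first column and one column per
#' sample. The sidecar metadata TSV maps `sample` to `variety`
#' (WF/RF/PF) and `stage` (bud/full_bloom). Every matrix sample must have
#' metadata; negative FPKM values are an error.
#'
#' @param path matrix TSV path.
#' @param metadata_path metadata TSV path.
#' @return an object of class `expression_table`: list with `values`
#'   (numeric matrix, genes x samples) and `samples` (metadata data.frame).
#' @export
read_expression_table <- function(path, metadata_path) {
  if (!file.exists(path)) stopf("expression table not found: %s", path)
  if (!file.exists(metadata_path)) stopf("metadata not found: %s", metadata_path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) stopf("duplicate gene id(s) in expression table")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric expression values")
  rownames(mat) <- genes
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stopf("missing FPKM at gene %s, sample %s", genes[idx[1]],
          colnames(mat)[idx[2]])
  }
  if (any(mat < 0)) {
    idx <- which(mat < 0, arr.ind = TRUE)[1, ]
    stopf("negative FPKM at gene %s, sample %s", genes[idx[1]],
          colnames(mat)[idx[2]])
  }
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "variety", "stage") %in% names(meta))) {
    stopf("metadata must have columns sample, variety, stage")
  }
  missing_meta <- setdiff(colnames(mat), meta$sample)
  if (length(missing_meta)) {
    stopf("sample(s) without metadata: %s", paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(colnames(mat), meta$sample), c("sample", "variety", "stage")]
  rownames(meta) <- NULL
  expression_table(mat, meta)
}

expression_table <- function(values, samples) {
  stopifnot(is.matrix(values), all(values >= 0),
            identical(colnames(values), samples$sample))
  structure(list(values = values, samples = samples),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(paste0(x$samples$variety, "/", x$samples$stage)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a newick tree with a partial leaf-to-subgroup label map
#'
#' The labels TSV (columns `leaf`, `group`) may cover any subset of leaves;
#' unlabeled leaves are recorded as `UC`. Labels must come from
#' I/IIa/IIb/IIc/IId/IIe/III, negative branch lengths and labels for
#' absent leaves are errors.
#'
#' @param path newick file with a single tree.
#' @param labels_path optional labels TSV; `NULL` means all leaves UC.
#' @return object of class `labeled_tree`: list with `tree` (an
#'   [ape::read.tree()] phylo) and `labels` (named character, one per leaf).
#' @export
read_newick <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stopf("newick file not found: %s", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stopf("malformed newick: %s", conditionMessage(e)))
  if (is.null(tree)) stopf("malformed newick in %s", path)
  if (inherits(tree, "multiPhylo")) stopf("expected a single tree in %s", path)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stopf("tree must have non-negative branch lengths")
  }
  if (any(!nzchar(tree$tip.label))) stopf("all leaves must be named")
  labels <- setNames(rep("UC", length(tree$tip.label)), tree$tip.label)
  if (!is.null(labels_path)) {
    lab <- read.delim(labels_path, stringsAsFactors = FALSE)
    if (!all(c("leaf", "group") %in% names(lab))) {
      stopf("labels TSV must have columns leaf, group")
    }
    unknown <- setdiff(lab$leaf, tree$tip.label)
    if (length(unknown)) {
      stopf("label(s) for leaves not in the tree: %s",
            paste(unknown, collapse = ", "))
    }
    bad <- setdiff(lab$group, setdiff(GROUP_LABELS, "UC"))
    if (length(bad)) stopf("unknown subgroup label(s): %s", paste(bad, collapse = ", "))
    labels[lab$leaf] <- lab$group
  }
  structure(list(tree = tree, labels = labels), class = "labeled_tree")
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  yaml::read_yaml(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
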